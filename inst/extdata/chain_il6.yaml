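# Adiposity -> inflammation -> depression chain, IL-6 path coefficients
nodes: [adiposity, inflammation, depression]
edges:
  - {from: adiposity, to: inflammation, coef: 0.274}
  - {from: inflammation, to: depression, coef: 0.125}
residual_variances:
  adiposity: 1.0
  inflammation: 1.0
  depression: 1.0
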