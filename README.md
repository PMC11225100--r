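# precisim

Covariate selection in observational immunopsychiatry is often done "to be
safe": adiposity is routinely added to models that estimate the association
between an inflammatory protein (such as IL-6 or C-reactive protein) and
depression symptoms, because adiposity plainly causes inflammation. But if
the plausible causal structure is a chain,

```
adiposity --a--> inflammation --b--> depression      (direct path c' = 0)
```

then adiposity is an *exposure-only ancestor*: it affects the outcome only
through the exposure. Adjusting for it cannot remove confounding (there is
none) — it only absorbs exposure variance and inflates the sampling variance
of the focal coefficient. `precisim` packages the machinery to quantify that
trade-off:

- **`dag_spec()` / `simulate_dataset()`** — linear-Gaussian DAGs as
  data-generating mechanisms, with exact implied covariances
  (`implied_covariance()`, Σ = (I−B)⁻¹ Ψ (I−B)⁻ᵀ) and seeded, reproducible
  sampling.
- **`classify_covariate()`** — the graph-based covariate-role classifier:
  confounder, mediator, collider, exposure-only ancestor, outcome-only
  ancestor, or disconnected.
- **`fit_mediation()`** — simple mediation with standardized coefficients
  (a, b, c′), the product-of-coefficients indirect effect a·b, and a
  percentile-bootstrap confidence interval.
- **`run_scenario()` / `run_study()`** — a deterministic Monte Carlo engine
  that fits the two competing models (depression ~ inflammation vs.
  depression ~ inflammation + adiposity) to every simulated dataset.
- **`summarize_performance()`** — simsum-style performance measures with
  Monte Carlo standard errors: bias, empirical SE, model SE, power, and the
  relative precision gain `100·((empSE_ref/empSE)² − 1)` with a
  leave-one-replication-out jackknife MCSE. `compare_se_paired()` gives the
  paired t comparison of reported SEs, and `analytic_precision_loss()` the
  closed-form large-sample loss `100·a²` (standardized exposure) or
  `100·a²/(1+a²)` (unit residual variances).

All user-facing functions take and return tibbles, fitted objects have
`tidy()`/`glance()` methods, and `plot_precision_gain()` /
`plot_se_distributions()` render the two standard result views. A thin
command-line front end lives at
`system.file("scripts", "precisim", package = "precisim")` with subcommands
`generate`, `mediate`, `run-study`, `summarize`, and `classify`.

## Worked example

Simulate one IL-6-like cohort, extract the mediation paths, then run a
1000-replication study at N = 500:

```r
library(precisim)

d <- simulate_dataset(dag_preset("il6", "standardized"), n = 549, seed = 42)
fit_mediation(d, "adiposity", "inflammation", "depression",
              n_boot = 5000, seed = 1)
#> <mediation_fit> adiposity -> inflammation -> depression  (n = 549)
#>   a = 0.1520 (p = 0.000351), b = 0.1339 (p = 0.00188), c' = -0.0600 (p = 0.162)
#>   indirect a*b = 0.0204, 95% percentile bootstrap CI [0.0052, 0.0406] (5000 resamples)

s   <- scenario("IL6_N500", a = 0.274, b = 0.125, n = 500, nsim = 1000)
res <- run_scenario(s, seed = 2024)
summarize_performance(res, true_value = 0.125)
#>   method     mean_estimate   bias  empse  modse power precision_gain_pct (mcse)
#>   unadjusted         0.123 -0.0022 0.0428 0.0432 0.814               0.00
#>   adjusted           0.123 -0.0018 0.0439 0.0449 0.782              -4.77 (1.61)

compare_se_paired(res)
#>   scenario_label method        t  df p.value mean_diff
#>   IL6_N500       adjusted -91.5  999       0  -0.00164
```

Reading: both models are unbiased for the true effect b = 0.125 (bias ≈ 0),
but the adjusted model's estimates scatter more (empirical SE 0.0439 vs
0.0428), its reported SEs are larger in essentially every replication
(paired t = −91.5), its power is lower (78% vs 81%), and its precision is
4.8% lower than the unadjusted reference (jackknife MCSE 1.6; the
large-sample value is `analytic_precision_loss(0.274, "unit_residual")` =
6.98%). Adjusting for the ancestor costs precision and buys nothing.

The bundled study configuration
(`system.file("extdata", "study_config.yaml", package = "precisim")`)
encodes the canonical six-scenario design: IL-6 (a = .274, b = .125) and CRP
(a = .429, b = .108) chains at N = 100, 250, 500 with 1000 replications
each.

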