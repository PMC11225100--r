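Package: precisim
Title: Precision Consequences of Covariate Adjustment on Causal Chains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how adjusting for an ancestor of the exposure
    changes the precision of a regression estimate under a linear-Gaussian
    causal chain. Provides a directed-acyclic-graph data-generating mechanism
    with implied covariance and seeded simulation, a covariate-role classifier
    (confounder, mediator, collider, exposure-only ancestor), simple mediation
    with standardized coefficients and a percentile-bootstrap confidence
    interval for the indirect effect, a reproducible Monte Carlo engine, and
    simsum-style performance summaries (bias, empirical and model standard
    errors, power, relative precision gain) with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
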