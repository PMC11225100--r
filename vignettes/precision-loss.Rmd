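---
title: "Covariate adjustment and precision loss on a causal chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate adjustment and precision loss on a causal chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precisim)
```

## The question

Suppose the world works like a chain: adiposity raises circulating levels of
an inflammatory protein, and the protein in turn raises depression symptoms,
with no direct adiposity → depression path. A researcher who wants the
inflammation → depression coefficient has two natural models:

* **unadjusted** — `depression ~ inflammation`;
* **adjusted** — `depression ~ inflammation + adiposity`.

Under the chain, adiposity is an *exposure-only ancestor*: it is not a
confounder (no open back-door path), so both models are unbiased for the
same estimand. The only thing adjustment changes is precision. Partialling
adiposity out of inflammation removes the share `R² = ρ²` of exposure
variance that adiposity explains, and the sampling variance of the focal
slope scales with the inverse of the residual exposure variance — the
familiar variance-inflation-factor arithmetic. `precisim` exists to state
that trade-off as a simulation study and as closed forms, and to check the
two against each other.

## The data-generating mechanism

A `dag_spec` stores nodes in topological order, a strictly lower-triangular
coefficient matrix `B` (`B[j, i]` is the path i → j), and positive residual
variances `Ψ`. The model is linear-Gaussian: each node is the linear
combination of its parents plus independent Gaussian noise. Its second
moments are exact:

$$\Sigma = (I - B)^{-1} \, \Psi \, (I - B)^{-\top},$$

which `implied_covariance()` computes by triangular solves and which the
sampler `simulate_dataset()` matches in the large-sample limit (a property
the test suite checks on random DAGs). Noise is Gaussian only — the
linear-Gaussian mechanism is the object of study, and no heavy-tailed
option is provided.

Two **variance conventions** are supported, because standardized path
coefficients can be embedded in a simulation two ways:

* `unit_residual` (default): all residual variances are 1 and the
  coefficients are used exactly as given. Downstream nodes then have total
  variance above 1 — e.g. `Var(inflammation) = 1 + a²` — and the implied
  exposure share explained by the ancestor is `ρ² = a²/(1 + a²)`.
* `standardized`: `standardize_residuals()` rescales residual variances,
  node by node in topological order, so every implied total variance is 1
  (`ψ_j = 1 −` variance explained by parents; infeasible and an error when
  that reaches 1). Coefficients are then standardized betas and `ρ² = a²`.

The default is `unit_residual` because it is the common behavior of SEM
simulation tooling when only path coefficients are supplied, and the
published precision-loss percentages are consistent with it; the
`standardized` option is a one-call switch, and both closed-form limits are
exposed (see below). The chain coefficients themselves default to the
cross-sectional mediation estimates for the two proteins: IL-6 a = .274,
b = .125; CRP a = .429, b = .108; direct path c′ = 0 in both (the direct
effect was null), configurable to any value.

**Seed contract.** Replication `r` of scenario `s` (1-based position in the
study) under master seed `m` uses the derived seed
`(m + 1000003·s + 7919·r) mod 2147483629`. Every replication is therefore
reproducible in isolation, and scenarios can be run alone, reordered, or
parallelized without changing a single draw. Within a replication the
residual matrix is drawn column-wise in one call, then nodes are filled in
topological order; this layout is part of the determinism contract.

## Covariate roles

`classify_covariate()` reads roles off the graph, using directed
reachability only:

* **confounder** — ancestor of both exposure and outcome via directed paths
  that bypass the exposure;
* **mediator** — descendant of the exposure and ancestor of the outcome;
* **collider** — descendant of both;
* **exposure-only ancestor** — ancestor of the exposure whose every
  directed path to the outcome passes through the exposure (the adiposity
  case); **outcome-only ancestor** symmetrically;
* **disconnected** otherwise.

The checks are ordered as listed, so a variable that is both a common cause
and on the mediating pathway is reported by its first matching (most
bias-relevant) role. Full d-separation over arbitrary conditioning sets,
latent variables, nonlinear structural equations and cyclic graphs are out
of scope; time-varying structures can be expressed as separate per-timepoint
DAGs.

## Mediation stage

`fit_mediation()` implements simple (single-mediator) mediation the way the
effect sizes feeding the simulation were extracted: z-standardize x, m, y
(sample SD, n−1 denominator), estimate `a` from m ~ x, `b` and `c′` jointly
from y ~ m + x, and report the product-of-coefficients indirect effect
`a·b`. Standardize-then-fit and fit-then-rescale coincide for OLS; the test
suite asserts the identity, along with `a·b + c′ = total` (exact for OLS on
standardized variables in this model). p-values are two-sided t with
`n − k − 1` degrees of freedom. Missing data are handled by listwise
deletion over the three analysis variables only.

The indirect-effect interval is a **percentile bootstrap**: resample rows
with replacement, recompute the standardized paths from the resample's
correlation matrix (an exact, cheaper equivalent of re-z-scoring and
refitting), and take empirical quantiles. Defaults: 5000 resamples, 95%
level, both configurable; the bootstrap is percentile rather than
bias-corrected because that is the standard default behavior for this model
class, and nothing finer was required of it. The interval is deterministic
given `seed`.

## The Monte Carlo engine and its performance measures

`run_scenario()` fits both models to every simulated dataset and stores the
focal (inflammation) coefficient's estimate, SE, and p-value in a long
tibble — the paired design matters, because the two methods' estimate
streams are strongly correlated within replications, and the precision
comparison should exploit that. Rank-deficient replications are recorded,
skipped (never resampled, which would bias the performance measures), and
the run aborts if more than 1% fail.

`summarize_performance()` follows the simsum conventions:

| measure | definition | MCSE |
|---|---|---|
| bias | mean(est) − b | — |
| empirical SE | SD of estimates (n−1) | empSE/√(2(n−1)) |
| model SE | √(mean(se²)) | — |
| power | share of p < α | √(p(1−p)/n) |
| precision gain | 100·((empSE_ref/empSE)² − 1) | leave-one-out jackknife |

α defaults to 0.05 two-sided; the estimand is the generating `b` (both
estimators target it when c′ = 0); the reference method's gain is exactly 0
by construction. The jackknife MCSE recomputes the gain with each
replication deleted from *both* paired streams, which is what makes the
reported uncertainty honest under the within-replication correlation.
`compare_se_paired()` is the matching paired t statistic on the reported
SEs, signed so that a negative value means the non-reference (adjusted)
SEs are larger.

`analytic_precision_loss(a, convention)` is the closed-form counterpart:
`100·a²` (standardized) or `100·a²/(1+a²)` (unit residuals). Two
qualifications worth knowing:

* It is a **large-N** limit. With Gaussian regressors the exact expected
  loss at sample size N is `ρ² + (1−ρ²)/(N−3)` — an inverse-Wishart moment
  of (XᵀX)⁻¹ — so at N = 100 the expected loss sits about one percentage
  point above the limit. The convergence test in the suite therefore runs
  at N = 1000, where the finite-N excess (~0.09 points) is an order of
  magnitude below the comparison band, with nsim = 10⁵ to bring the Monte
  Carlo error near 0.2 points.
* At the study's own size (nsim = 1000) the loss estimate carries a Monte
  Carlo SE of roughly 1.6 (IL-6) to 2.2 (CRP) percentage points — any two
  independent runs of the same design, and equally any published set of
  per-N losses, should be expected to scatter by that much around the
  limit. The package reports that MCSE rather than pretending the point
  value is sharp.

## Problem sizes used by the suite

The unit tests run small designs (tens to hundreds of replications,
n up to 10⁵ for closed-form checks). The full-scale checks run the bundled
six-scenario study at nsim = 1000 (≈ 12,000 regressions, a few seconds),
the nsim = 10⁵ convergence runs at N = 1000 described above, a
100-replication bootstrap-power study at n = 549, and parameter recovery at
n = 50,000. These sizes were chosen so each quantity's Monte Carlo error is
small relative to the tolerance it is compared against.

## What the generator does and does not emulate

The synthetic mechanism reproduces the *correlational skeleton* the chain
hypothesis implies: standardized effect sizes, Gaussian marginals, exact
linearity, complete data. Real biomarker data differ in ways that matter
for other questions — log-normal protein distributions, detection-limit
censoring, platform batch effects, item-sum outcome scales with bounded
support, missingness that is not completely at random. Passing tests here
certify the statistical machinery and the precision arithmetic under the
stated mechanism; they do not certify that any particular empirical dataset
follows the chain, which is exactly why the covariate-role classifier takes
the graph as an explicit input rather than assuming it.

## Known limitations

* Only simple mediation (one mediator, no moderation, no repeated
  measures).
* OLS with classical SEs only — no robust/sandwich options, no GLMs.
* The classifier is role-labeling relative to one exposure-outcome pair,
  not a general adjustment-set search.
* Confidence-interval coverage is computable from the stored fields but is
  not a headline summary.
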