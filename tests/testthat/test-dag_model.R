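test_that("implied covariance solves the structural equations", {
  # no edges: covariance is the residual-variance diagonal
  d0 <- dag_spec(c("a", "b", "c"))
  expect_equal(unname(implied_covariance(d0)), diag(3))

  # chain with a = b = .5, unit residuals; values verified against a
  # 10^6-draw sample-covariance oracle
  sigma <- implied_covariance(chain_dag(0.5, 0.5))
  expect_equal(sigma["inflammation", "inflammation"], 1.25)
  expect_equal(sigma["depression", "depression"], 1.3125)
  expect_equal(sigma["adiposity", "inflammation"], 0.5)
  expect_equal(sigma["adiposity", "depression"], 0.25)
  expect_equal(sigma["inflammation", "depression"], 0.625)

  # chain cross-covariance of the endpoints is the coefficient product:
  # the published standardized indirect effect for the IL-6 paths
  sigma_il6 <- implied_covariance(chain_dag(0.274, 0.125))
  expect_equal(sigma_il6["adiposity", "depression"], 0.274 * 0.125)
  expect_equal(round(sigma_il6["adiposity", "depression"], 3), 0.034)
})

test_that("implied covariance is invariant to a consistent relabeling", {
  dag <- random_dag(11, p = 4)
  sigma <- implied_covariance(dag)
  perm <- c("v1", "v2", "v3", "v4") # topological order must be preserved,
  renamed <- dag                    # so relabel names only
  renamed$nodes <- paste0("w", 1:4)
  dimnames(renamed$beta) <- list(renamed$nodes, renamed$nodes)
  names(renamed$psi) <- renamed$nodes
  expect_equal(unname(implied_covariance(renamed)), unname(sigma))
})

test_that("a cyclic coefficient matrix is rejected naming the edge", {
  expect_error(
    dag_spec(c("x", "y"), data.frame(from = "y", to = "x", coef = 0.5)),
    "y -> x"
  )
  bad <- chain_dag(0.3, 0.3)
  bad$beta["adiposity", "depression"] <- 0.2 # upper-triangular entry
  expect_error(implied_covariance(bad), "depression -> adiposity")
})

test_that("standardize_residuals gives unit implied variances", {
  d0 <- dag_spec(c("a", "b"))
  expect_equal(standardize_residuals(d0)$psi, c(a = 1, b = 1))

  # closed form for a chain: psi_M = 1 - a^2, psi_Y = 1 - b^2 (c' = 0)
  std <- standardize_residuals(chain_dag(0.5, 0.5))
  expect_equal(unname(std$psi), c(1, 0.75, 0.75))
  expect_equal(diag(implied_covariance(std)), c(adiposity = 1,
                                                inflammation = 1,
                                                depression = 1))
  std_il6 <- standardize_residuals(chain_dag(0.274, 0.125))
  expect_equal(unname(std_il6$psi["inflammation"]), 1 - 0.274^2)

  # round trip on random DAGs: unit diagonal to machine precision when
  # feasible, the documented error when parents explain >= 1 of a variance
  for (seed in 1:6) {
    raw <- random_dag(seed, max_coef = 0.5)
    dag <- tryCatch(standardize_residuals(raw), error = function(e) e)
    if (inherits(dag, "error")) {
      expect_match(conditionMessage(dag), "explained variance")
    } else {
      expect_equal(unname(diag(implied_covariance(dag))),
                   rep(1, length(dag$nodes)), tolerance = 1e-12)
    }
  }

  # infeasible when parents already explain >= 1 of the variance
  big <- dag_spec(c("x", "y"),
                  data.frame(from = "x", to = "y", coef = 1.4))
  expect_error(standardize_residuals(big), "explained variance")
})

test_that("simulate_dataset draws i.i.d. rows matching the mechanism", {
  dag <- dag_preset("il6")
  expect_identical(simulate_dataset(dag, 50, seed = 3),
                   simulate_dataset(dag, 50, seed = 3))
  expect_error(simulate_dataset(dag, -1, seed = 1), "non-negative")

  empty <- simulate_dataset(dag, 0, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("adiposity", "inflammation", "depression"))

  # no edges: columns are independent
  indep <- simulate_dataset(dag_spec(c("a", "b", "c")), 1e4, seed = 4)
  cors <- cor(as.matrix(indep))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.03)

  # unit-residual convention: corr(A, M) = a / sqrt(1 + a^2)
  crp <- simulate_dataset(dag_preset("crp"), 1e5, seed = 5)
  expect_equal(cor(crp$adiposity, crp$inflammation), 0.429 / sqrt(1.184),
               tolerance = 0.01 / 0.394)
})

test_that("sample covariance converges to the implied covariance", {
  n <- 4e4
  for (seed in 1:6) {
    dag <- random_dag(100 + seed)
    sigma <- implied_covariance(dag)
    s <- mc_covariance(dag, n, seed = 200 + seed)
    expect_lt(max(abs(s - sigma)), 4 / sqrt(n) * max(1, max(abs(sigma))))
  }
})

test_that("covariate roles follow the three fundamental structures", {
  # chain: exposure -> covariate -> outcome => mediator
  chain <- dag_spec(c("A", "B", "C"),
                    data.frame(from = c("A", "B"), to = c("B", "C"),
                               coef = 0.4))
  expect_identical(classify_covariate(chain, "A", "C", "B"), "mediator")
  # fork: covariate causes both => confounder
  fork <- dag_spec(c("B", "A", "C"),
                   data.frame(from = "B", to = c("A", "C"), coef = 0.4))
  expect_identical(classify_covariate(fork, "A", "C", "B"), "confounder")
  # inverted fork: covariate caused by both => collider
  invf <- dag_spec(c("A", "C", "B"),
                   data.frame(from = c("A", "C"), to = "B", coef = 0.4))
  expect_identical(classify_covariate(invf, "A", "C", "B"), "collider")
})

test_that("covariate roles match the worked graph examples", {
  stress <- dag_spec(c("stress", "inflammation", "depression"),
                     data.frame(from = "stress",
                                to = c("inflammation", "depression"),
                                coef = c(0.3, 0.3)))
  expect_identical(
    classify_covariate(stress, "inflammation", "depression", "stress"),
    "confounder")

  vac <- dag_spec(c("vaccination", "exercise", "inflammation"),
                  data.frame(from = c("vaccination", "exercise"),
                             to = "inflammation", coef = c(0.3, 0.3)))
  expect_identical(
    classify_covariate(vac, "vaccination", "exercise", "inflammation"),
    "collider")

  expect_identical(
    classify_covariate(dag_preset("il6"), "inflammation", "depression",
                       "adiposity"),
    "exposure_only_ancestor")

  # symmetric outcome-only ancestor and a disconnected node
  oo <- dag_spec(c("Z", "X", "Y"),
                 data.frame(from = c("Z", "X"), to = c("Y", "Y"),
                            coef = 0.3))
  expect_identical(classify_covariate(oo, "X", "Y", "Z"),
                   "outcome_only_ancestor")
  disc <- dag_spec(c("Z", "X", "Y"),
                   data.frame(from = "X", to = "Y", coef = 0.3))
  expect_identical(classify_covariate(disc, "X", "Y", "Z"), "disconnected")

  expect_error(classify_covariate(disc, "X", "Y", "missing"), "not in DAG")
  expect_error(classify_covariate(disc, "X", "Y", "X"), "must differ")
})

test_that("adjusting for a collider induces a spurious association", {
  # marginally independent causes of a common effect
  dag <- dag_spec(c("x", "y", "collider"),
                  data.frame(from = c("x", "y"), to = "collider",
                             coef = c(0.6, 0.6)))
  d <- simulate_dataset(dag, 1e4, seed = 9)
  marginal <- fit_ols(d$y, cbind(x = d$x))
  adjusted <- fit_ols(d$y, cbind(x = d$x, collider = d$collider))
  expect_lt(abs(marginal$statistic["x"]), 3)       # null marginal effect
  expect_gt(abs(adjusted$statistic["x"]), 2)       # collider bias
})

test_that("DAG YAML files round-trip through the reader", {
  path <- system.file("extdata", "chain_il6.yaml", package = "precisim")
  dag <- read_dag_yaml(path)
  expect_identical(dag$nodes, c("adiposity", "inflammation", "depression"))
  expect_equal(dag$beta["inflammation", "adiposity"], 0.274)
  expect_equal(unname(dag$psi), c(1, 1, 1))

  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nodes: [a, b]",
               "edges:",
               "  - {from: a, to: b, coef: -0.25}"), tmp)
  dag2 <- read_dag_yaml(tmp)
  expect_equal(dag2$beta["b", "a"], -0.25)
})
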