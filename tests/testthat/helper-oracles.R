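# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: plain normal equations, explicit loops, and
# direct arithmetic.

# textbook OLS via explicit normal equations (intercept prepended)
ols_oracle <- function(y, x = NULL) {
  design <- if (is.null(x)) cbind(rep(1, length(y))) else cbind(1, as.matrix(x))
  xtx <- t(design) %*% design
  beta <- solve(xtx, t(design) %*% y)
  resid <- y - design %*% beta
  df <- length(y) - ncol(design)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(solve(xtx)))
  list(beta = drop(beta), se = unname(se), sigma2 = sigma2, df = df)
}

# a random small DAG in guaranteed topological order
random_dag <- function(seed, p = sample(3:5, 1), max_coef = 0.8) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(p))
  edges <- NULL
  for (j in 2:p) {
    parents <- which(stats::runif(j - 1) < 0.6)
    if (length(parents)) {
      edges <- rbind(edges, data.frame(
        from = nodes[parents], to = nodes[j],
        coef = round(stats::runif(length(parents), -max_coef, max_coef), 2)
      ))
    }
  }
  dag_spec(nodes, edges,
           residual_variances = round(stats::runif(p, 0.5, 2), 2))
}

# sample-covariance Monte Carlo oracle for the implied second moments
mc_covariance <- function(dag, n, seed) {
  stats::cov(as.matrix(simulate_dataset(dag, n, seed)))
}
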