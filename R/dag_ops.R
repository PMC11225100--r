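#' Implied covariance matrix of a linear-Gaussian DAG
#'
#' Solves the structural equations for the second moments: with coefficient
#' matrix B and diagonal residual-variance matrix Psi, the implied covariance
#' is `(I - B)^-1 Psi (I - B)^-T`. Equivalent to Wright's path-tracing rules
#' on acyclic graphs.
#'
#' @param dag A [dag_spec()].
#' @return A symmetric numeric matrix with node names on both dimensions.
#' @examples
#' implied_covariance(chain_dag(a = 0.5, b = 0.5))
#' @export
implied_covariance <- function(dag) {
  validate_dag(dag)
  p <- length(dag$nodes)
  iminusb <- diag(p) - dag$beta
  # triangular system: forwardsolve is exact and cheap
  ainv <- forwardsolve(iminusb, diag(p))
  sigma <- ainv %*% diag(dag$psi, p) %*% t(ainv)
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(dag$nodes, dag$nodes)
  sigma
}

#' Rescale residual variances so every node has unit total variance
#'
#' Keeps the path coefficients fixed and solves, node by node in topological
#' order, for the residual variance that makes the implied total variance 1.
#' With unit-variance parents this turns the coefficients into standardized
#' betas. Fails when a node's variance explained by its parents is already
#' >= 1, in which case no positive residual variance exists.
#'
#' @param dag A [dag_spec()].
#' @return A [dag_spec()] with identical coefficients and rescaled residual
#'   variances; `implied_covariance()` of the result has a unit diagonal.
#' @examples
#' standardize_residuals(chain_dag(a = 0.5, b = 0.5))
#' @export
standardize_residuals <- function(dag) {
  validate_dag(dag)
  p <- length(dag$nodes)
  sigma <- matrix(0, p, p)
  psi <- numeric(p)
  for (j in seq_len(p)) {
    bj <- dag$beta[j, seq_len(p)]
    explained <- if (j == 1L) 0 else
      drop(bj[1:(j - 1)] %*% sigma[1:(j - 1), 1:(j - 1), drop = FALSE] %*%
             bj[1:(j - 1)])
    if (explained >= 1) {
      stop("cannot standardize: explained variance for node `",
           dag$nodes[j], "` is ", signif(explained, 4),
           " >= 1", call. = FALSE)
    }
    psi[j] <- 1 - explained
    if (j > 1L) {
      cross <- sigma[1:(j - 1), 1:(j - 1), drop = FALSE] %*% bj[1:(j - 1)]
      sigma[j, 1:(j - 1)] <- cross
      sigma[1:(j - 1), j] <- cross
    }
    sigma[j, j] <- 1
  }
  names(psi) <- dag$nodes
  out <- dag
  out$psi <- psi
  out
}

# residuals drawn as an n x p matrix in one rnorm call, nodes then filled in
# topological order; this layout is the determinism contract for a given seed
simulate_matrix <- function(dag, n) {
  p <- length(dag$nodes)
  eps <- matrix(stats::rnorm(n * p), n, p)
  eps <- sweep(eps, 2L, sqrt(dag$psi), `*`)
  x <- matrix(0, n, p, dimnames = list(NULL, dag$nodes))
  for (j in seq_len(p)) {
    parents <- which(dag$beta[j, ] != 0)
    xj <- eps[, j]
    if (length(parents)) {
      xj <- xj + x[, parents, drop = FALSE] %*% dag$beta[j, parents]
    }
    x[, j] <- xj
  }
  x
}

#' Draw a seeded i.i.d. sample from a linear-Gaussian DAG
#'
#' Each row is an independent draw; each node equals the linear combination
#' of its parents plus Gaussian noise with the node's residual variance.
#' Identical `(dag, n, seed)` input gives bit-identical output.
#'
#' @param dag A [dag_spec()].
#' @param n Number of rows to draw (`n = 0` gives an empty table with the
#'   node columns).
#' @param seed Integer seed controlling the draw.
#' @return A tibble with one column per node.
#' @examples
#' simulate_dataset(dag_preset("il6"), n = 5, seed = 1)
#' @export
simulate_dataset <- function(dag, n, seed) {
  validate_dag(dag)
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  if (n == 0L) {
    empty <- rep(list(numeric(0)), length(dag$nodes))
    names(empty) <- dag$nodes
    return(tibble::as_tibble(empty))
  }
  set.seed(as.integer(seed))
  tibble::as_tibble(simulate_matrix(dag, as.integer(n)))
}

descendants_of <- function(beta, start, drop = integer(0)) {
  # BFS over the child relation; `drop` removes nodes (blocks paths through
  # them); returns indices reachable from `start`, excluding `start` itself
  p <- nrow(beta)
  adj <- beta != 0 # adj[j, i]: edge i -> j
  if (length(drop)) {
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  seen <- rep(FALSE, p)
  frontier <- start
  while (length(frontier)) {
    nxt <- which(apply(adj[, frontier, drop = FALSE], 1L, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[start] <- FALSE
  which(seen)
}

#' Classify a covariate's causal role for an exposure-outcome pair
#'
#' Decides, from the graph alone, whether a third variable is a confounder
#' (common cause of exposure and outcome through paths that bypass the
#' exposure), a mediator (caused by the exposure, causing the outcome), a
#' collider (common effect of both), an exposure-only ancestor (causes the
#' exposure, and reaches the outcome only through it -- the adiposity case,
#' where adjustment buys no bias reduction but costs precision), an
#' outcome-only ancestor, or disconnected from the pair.
#'
#' @param dag A [dag_spec()].
#' @param exposure,outcome,covariate Node names; all three must be distinct
#'   and present in the DAG.
#' @return A single string, one of `"confounder"`, `"mediator"`,
#'   `"collider"`, `"exposure_only_ancestor"`, `"outcome_only_ancestor"`,
#'   `"disconnected"`.
#' @examples
#' fork <- dag_spec(c("stress", "inflammation", "depression"),
#'   data.frame(from = "stress", to = c("inflammation", "depression"),
#'              coef = 0.3))
#' classify_covariate(fork, "inflammation", "depression", "stress")
#' @export
classify_covariate <- function(dag, exposure, outcome, covariate) {
  validate_dag(dag)
  for (nm in c(exposure, outcome, covariate)) {
    if (!nm %in% dag$nodes) {
      stop("node not in DAG: `", nm, "`", call. = FALSE)
    }
  }
  if (covariate == exposure || covariate == outcome) {
    stop("`covariate` must differ from both `exposure` and `outcome`",
         call. = FALSE)
  }
  if (exposure == outcome) {
    stop("`exposure` and `outcome` must differ", call. = FALSE)
  }
  e <- match(exposure, dag$nodes)
  o <- match(outcome, dag$nodes)
  z <- match(covariate, dag$nodes)

  desc_z <- descendants_of(dag$beta, z)
  desc_z_no_e <- descendants_of(dag$beta, z, drop = e)
  desc_z_no_o <- descendants_of(dag$beta, z, drop = o)
  desc_e <- descendants_of(dag$beta, e)
  desc_o <- descendants_of(dag$beta, o)

  anc_of_e <- e %in% desc_z
  anc_of_o <- o %in% desc_z
  anc_of_o_bypassing_e <- o %in% desc_z_no_e
  anc_of_e_bypassing_o <- e %in% desc_z_no_o
  desc_of_e <- z %in% desc_e
  desc_of_o <- z %in% desc_o

  if (anc_of_e && anc_of_o_bypassing_e) return("confounder")
  if (desc_of_e && anc_of_o) return("mediator")
  if (desc_of_e && desc_of_o) return("collider")
  if (anc_of_e && !anc_of_o_bypassing_e) return("exposure_only_ancestor")
  if (anc_of_o && !anc_of_e_bypassing_o) return("outcome_only_ancestor")
  "disconnected"
}

covariate_roles <- function() {
  c("confounder", "mediator", "collider", "exposure_only_ancestor",
    "outcome_only_ancestor", "disconnected")
}
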