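#' Linear-Gaussian DAG specification
#'
#' A `dag_spec` is the data-generating mechanism used throughout the package:
#' a set of nodes in topological order, a strictly lower-triangular matrix of
#' path coefficients, and a strictly positive residual variance per node. Each
#' node is a linear combination of its parents plus independent Gaussian
#' noise.
#'
#' @param nodes Character vector of unique node names, in topological order
#'   (every edge points from an earlier to a later node).
#' @param edges A data frame with columns `from`, `to`, `coef` listing the
#'   directed edges and their path coefficients. May be empty.
#' @param residual_variances Named numeric vector of residual variances, or a
#'   single number recycled to all nodes. Unnamed scalar defaults to 1 for
#'   every node. All values must be strictly positive.
#'
#' @return An object of class `dag_spec` with elements `nodes`, `beta`
#'   (square coefficient matrix, entry `[j, i]` = coefficient on the edge
#'   from node `i` to node `j`), and `psi` (named residual-variance vector).
#' @examples
#' dag <- dag_spec(
#'   nodes = c("adiposity", "inflammation", "depression"),
#'   edges = data.frame(
#'     from = c("adiposity", "inflammation"),
#'     to   = c("inflammation", "depression"),
#'     coef = c(0.274, 0.125)
#'   )
#' )
#' implied_covariance(dag)
#' @export
dag_spec <- function(nodes, edges = NULL, residual_variances = 1) {
  if (!is.character(nodes) || length(nodes) < 1L) {
    stop("`nodes` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(nodes)) {
    stop("node names must be unique: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  }
  p <- length(nodes)
  beta <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && nrow(as.data.frame(edges)) > 0L) {
    edges <- as.data.frame(edges)
    stopifnot(all(c("from", "to", "coef") %in% names(edges)))
    for (k in seq_len(nrow(edges))) {
      from <- as.character(edges$from[k])
      to <- as.character(edges$to[k])
      if (!from %in% nodes || !to %in% nodes) {
        stop("edge references unknown node: ", from, " -> ", to, call. = FALSE)
      }
      i <- match(from, nodes)
      j <- match(to, nodes)
      if (j <= i) {
        stop("edge violates the topological node order (cycle or ",
             "self-loop): ", from, " -> ", to, call. = FALSE)
      }
      beta[j, i] <- as.numeric(edges$coef[k])
    }
  }
  psi <- residual_variances
  if (length(psi) == 1L && is.null(names(psi))) psi <- rep(psi, p)
  if (!is.null(names(psi))) {
    full <- rep(1, p)
    names(full) <- nodes
    unknown <- setdiff(names(psi), nodes)
    if (length(unknown)) {
      stop("residual variance given for unknown node: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    full[names(psi)] <- psi
    psi <- full
  }
  if (length(psi) != p) {
    stop("`residual_variances` must have one entry per node", call. = FALSE)
  }
  names(psi) <- nodes
  if (any(!is.finite(psi)) || any(psi <= 0)) {
    stop("residual variances must be strictly positive and finite",
         call. = FALSE)
  }
  if (any(!is.finite(beta))) stop("path coefficients must be finite",
                                  call. = FALSE)
  structure(list(nodes = nodes, beta = beta, psi = psi), class = "dag_spec")
}

validate_dag <- function(dag) {
  if (!inherits(dag, "dag_spec")) {
    stop("expected a `dag_spec` object", call. = FALSE)
  }
  bad <- which(dag$beta[upper.tri(dag$beta, diag = TRUE)] != 0)
  if (length(bad)) {
    idx <- which(dag$beta != 0 & upper.tri(dag$beta, diag = TRUE),
                 arr.ind = TRUE)[1, ]
    stop("coefficient matrix is not strictly lower-triangular; offending ",
         "edge: ", dag$nodes[idx[2]], " -> ", dag$nodes[idx[1]],
         call. = FALSE)
  }
  invisible(dag)
}

#' @export
print.dag_spec <- function(x, ...) {
  cat("<dag_spec> ", length(x$nodes), " nodes: ",
      paste(x$nodes, collapse = " -> "), "\n", sep = "")
  ed <- which(x$beta != 0, arr.ind = TRUE)
  if (nrow(ed)) {
    for (k in seq_len(nrow(ed))) {
      cat(sprintf("  %s -> %s  (%.4g)\n", x$nodes[ed[k, 2]],
                  x$nodes[ed[k, 1]], x$beta[ed[k, 1], ed[k, 2]]))
    }
  } else {
    cat("  (no edges)\n")
  }
  cat("  residual variances:",
      paste(sprintf("%s=%.4g", x$nodes, x$psi), collapse = ", "), "\n")
  invisible(x)
}

#' Three-node causal chain adiposity -> inflammation -> depression
#'
#' Convenience constructor for the canonical chain with path coefficient `a`
#' from adiposity to inflammation, `b` from inflammation to depression, and an
#' optional direct path `c_prime` from adiposity to depression. Column names
#' are fixed to `adiposity`, `inflammation`, `depression`.
#'
#' @param a Path coefficient adiposity -> inflammation.
#' @param b Path coefficient inflammation -> depression.
#' @param c_prime Direct path adiposity -> depression (default 0: the chain
#'   hypothesis, where the covariate affects the outcome only through the
#'   exposure).
#' @param variance_convention `"unit_residual"` (default; all residual
#'   variances 1, so coefficients are used exactly as given and downstream
#'   nodes have total variance above 1) or `"standardized"` (residual
#'   variances rescaled so every node has implied total variance 1 and the
#'   coefficients are standardized betas).
#' @return A [dag_spec()].
#' @examples
#' chain_dag(a = 0.274, b = 0.125)
#' @export
chain_dag <- function(a, b, c_prime = 0,
                      variance_convention = c("unit_residual",
                                              "standardized")) {
  variance_convention <- match.arg(variance_convention)
  dag <- dag_spec(
    nodes = c("adiposity", "inflammation", "depression"),
    edges = data.frame(
      from = c("adiposity", "inflammation", "adiposity"),
      to = c("inflammation", "depression", "depression"),
      coef = c(a, b, c_prime)
    )
  )
  if (variance_convention == "standardized") dag <- standardize_residuals(dag)
  dag
}

#' Preset chain mechanisms for the two inflammatory proteins
#'
#' Standardized path coefficients estimated in the cross-sectional mediation
#' stage: interleukin-6 (`"il6"`, a = .274, b = .125) and C-reactive protein
#' (`"crp"`, a = .429, b = .108), each with a null direct path.
#'
#' @param preset `"il6"` or `"crp"`.
#' @inheritParams chain_dag
#' @return A [dag_spec()].
#' @export
dag_preset <- function(preset = c("il6", "crp"),
                       variance_convention = c("unit_residual",
                                               "standardized")) {
  preset <- match.arg(preset)
  cf <- preset_coefficients(preset)
  chain_dag(a = cf$a, b = cf$b, c_prime = cf$c_prime,
            variance_convention = match.arg(variance_convention))
}

preset_coefficients <- function(preset) {
  switch(preset,
    il6 = list(a = 0.274, b = 0.125, c_prime = 0),
    crp = list(a = 0.429, b = 0.108, c_prime = 0),
    stop("unknown preset: ", preset, call. = FALSE)
  )
}

#' Read a DAG specification from a YAML file
#'
#' The file must contain `nodes:` (ordered list), `edges:` (list of mappings
#' with `from`, `to`, `coef`), and optionally `residual_variances:` (a map
#' from node name to variance; unlisted nodes default to 1).
#'
#' @param path Path to the YAML file.
#' @return A [dag_spec()].
#' @export
read_dag_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$nodes)) stop("DAG file lacks `nodes:`", call. = FALSE)
  edges <- NULL
  if (!is.null(spec$edges) && length(spec$edges)) {
    edges <- dplyr::bind_rows(lapply(spec$edges, function(e) {
      tibble::tibble(from = e$from, to = e$to, coef = as.numeric(e$coef))
    }))
  }
  psi <- 1
  if (!is.null(spec$residual_variances)) {
    psi <- unlist(spec$residual_variances)
  }
  dag_spec(nodes = as.character(unlist(spec$nodes)), edges = edges,
           residual_variances = psi)
}
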