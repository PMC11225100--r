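#' Z-standardize columns of a data frame
#'
#' Centers each named column to mean 0 and scales to sample standard
#' deviation 1 (denominator n - 1). Other columns are untouched.
#'
#' @param data A data frame.
#' @param columns Character vector of column names to standardize.
#' @return A tibble of the same shape.
#' @examples
#' zstandardize(data.frame(x = 1:3, y = c(10, 20, 30)), "x")
#' @export
zstandardize <- function(data, columns) {
  require_columns(data, columns)
  out <- tibble::as_tibble(data)
  for (col in columns) {
    v <- out[[col]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("column `", col, "` has zero variance; cannot standardize",
           call. = FALSE)
    }
    out[[col]] <- (v - mean(v)) / s
  }
  out
}

# standardized paths from a 3x3 correlation matrix of (x, m, y):
# a = r_xm; b, c' from the normal equations of y ~ m + x on unit-variance
# variables. Scale invariance makes this exactly the z-score-then-OLS fit.
paths_from_correlation <- function(r_xm, r_xy, r_my) {
  det <- 1 - r_xm^2
  b <- (r_my - r_xy * r_xm) / det
  c_prime <- (r_xy - r_my * r_xm) / det
  c(a = r_xm, b = b, c_prime = c_prime, indirect = r_xm * b, total = r_xy)
}

paths_from_data <- function(x, m, y) {
  paths_from_correlation(stats::cor(x, m), stats::cor(x, y), stats::cor(m, y))
}

#' Simple mediation with standardized coefficients and bootstrap CI
#'
#' Fits the single-mediator model x -> m -> y by ordinary least squares on
#' z-standardized variables: `a` is the slope of m on x, `b` and `c_prime`
#' come from the joint regression of y on m and x, and the indirect effect is
#' the product `a * b`. The confidence interval for the indirect effect is a
#' percentile bootstrap: rows are resampled with replacement, the paths
#' refitted, and the empirical quantiles taken at `(1 - ci_level)/2` and
#' `(1 + ci_level)/2`. Rows with a missing value in any of the three analysis
#' variables are dropped (listwise deletion).
#'
#' @param data A data frame.
#' @param x,m,y Column names of the predictor, mediator, and outcome.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param ci_level Confidence level for the percentile interval (default
#'   0.95).
#' @return An object of class `mediation_fit` with standardized estimates
#'   `a_hat`, `b_hat`, `c_prime_hat`, `indirect_hat` (= `a_hat * b_hat`),
#'   `total_hat`, per-path standard errors and two-sided t p-values,
#'   percentile CI bounds `ci_low`/`ci_high`, and bookkeeping fields
#'   (`n_used`, `n_boot`, `ci_level`, `seed`).
#' @examples
#' d <- simulate_dataset(dag_preset("il6", "standardized"), 500, seed = 7)
#' fit <- fit_mediation(d, "adiposity", "inflammation", "depression",
#'                      n_boot = 200, seed = 1)
#' tidy(fit)
#' @export
fit_mediation <- function(data, x, m, y, n_boot = 5000, seed = 1,
                          ci_level = 0.95) {
  require_columns(data, c(x, m, y))
  if (x == m || x == y || m == y) {
    stop("`x`, `m`, `y` must name three distinct columns", call. = FALSE)
  }
  if (ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must be in (0, 1)", call. = FALSE)
  }
  keep <- stats::complete.cases(data[, c(x, m, y)])
  d <- data[keep, c(x, m, y)]
  n <- nrow(d)
  if (n < 10L) {
    stop("need at least 10 complete rows; have ", n, call. = FALSE)
  }
  for (col in c(x, m, y)) {
    if (stats::sd(d[[col]]) == 0) {
      stop("column `", col, "` has zero variance", call. = FALSE)
    }
  }
  z <- zstandardize(d, c(x, m, y))
  col <- function(v, nm) `colnames<-`(cbind(v), nm)
  fit_a <- fit_ols(z[[m]], col(z[[x]], x))
  fit_by <- fit_ols(z[[y]], cbind(col(z[[m]], m), col(z[[x]], x)))
  fit_tot <- fit_ols(z[[y]], col(z[[x]], x))
  a_hat <- unname(fit_a$coefficients[x])
  b_hat <- unname(fit_by$coefficients[m])
  c_prime_hat <- unname(fit_by$coefficients[x])
  total_hat <- unname(fit_tot$coefficients[x])

  xv <- d[[x]]; mv <- d[[m]]; yv <- d[[y]]
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    pp <- paths_from_data(xv[idx], mv[idx], yv[idx])
    pp[["indirect"]]
  }, numeric(1))
  probs <- c((1 - ci_level) / 2, (1 + ci_level) / 2)
  ci <- unname(stats::quantile(boot, probs, names = FALSE, type = 7))

  structure(
    list(
      a_hat = a_hat, b_hat = b_hat, c_prime_hat = c_prime_hat,
      indirect_hat = a_hat * b_hat, total_hat = total_hat,
      se = c(a = unname(fit_a$se[x]), b = unname(fit_by$se[m]),
             c_prime = unname(fit_by$se[x])),
      p = c(a = unname(fit_a$p.value[x]), b = unname(fit_by$p.value[m]),
            c_prime = unname(fit_by$p.value[x])),
      ci_low = ci[1], ci_high = ci[2],
      n_boot = as.integer(n_boot), ci_level = ci_level,
      seed = as.integer(seed), n_used = n, n_input = nrow(data),
      vars = c(x = x, m = m, y = y)
    ),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit> ", x$vars["x"], " -> ", x$vars["m"], " -> ",
      x$vars["y"], "  (n = ", x$n_used, ")\n", sep = "")
  cat(sprintf("  a = %.4f (p = %.3g), b = %.4f (p = %.3g), c' = %.4f (p = %.3g)\n",
              x$a_hat, x$p["a"], x$b_hat, x$p["b"], x$c_prime_hat,
              x$p["c_prime"]))
  cat(sprintf("  indirect a*b = %.4f, %d%% percentile bootstrap CI [%.4f, %.4f] (%d resamples)\n",
              x$indirect_hat, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$n_boot))
  invisible(x)
}

#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c_prime", "indirect", "total"),
    estimate = c(x$a_hat, x$b_hat, x$c_prime_hat, x$indirect_hat,
                 x$total_hat),
    std.error = c(unname(x$se), NA_real_, NA_real_),
    p.value = c(unname(x$p), NA_real_, NA_real_),
    ci_low = c(NA_real_, NA_real_, NA_real_, x$ci_low, NA_real_),
    ci_high = c(NA_real_, NA_real_, NA_real_, x$ci_high, NA_real_)
  )
}

#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_input = x$n_input, n_boot = x$n_boot,
                 ci_level = x$ci_level, seed = x$seed)
}
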