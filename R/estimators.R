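#' Ordinary least squares with closed-form coefficient standard errors
#'
#' Fits `y` on the named predictor columns plus an intercept. Coefficient
#' standard errors are the classical `sqrt(sigma2 * diag((X'X)^-1))` with
#' `sigma2 = RSS / (n - p)`; p-values are two-sided from the t distribution
#' on the residual degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param x Numeric matrix (or data frame) of predictors with column names;
#'   `NULL` fits the intercept-only model.
#' @return An object of class `ols_fit`: a list with `coefficients` (named),
#'   `se`, `statistic`, `p.value`, `df.residual`, `sigma2` (residual
#'   variance), and `nobs`.
#' @examples
#' fit <- fit_ols(c(1, 3, 5), cbind(x = 0:2))
#' tidy(fit)
#' @export
fit_ols <- function(y, x = NULL) {
  if (is.null(x)) x <- matrix(numeric(0), length(y), 0L)
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0L) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  n <- length(y)
  if (nrow(x) != n) stop("`y` and `x` must have the same length", call. = FALSE)
  design <- cbind(`(Intercept)` = 1, x)
  p <- ncol(design)
  if (n <= p) {
    stop("too few observations: n = ", n, " with ", p, " coefficients",
         call. = FALSE)
  }
  fit <- stats::lm.fit(design, y)
  if (fit$rank < p) {
    stop("design matrix is rank deficient (collinear predictors)",
         call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  xtx_inv <- chol2inv(rmat)
  se <- sqrt(sigma2 * diag(xtx_inv))
  est <- fit$coefficients
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(
    list(coefficients = est, se = stats::setNames(se, names(est)),
         statistic = stats::setNames(tstat, names(est)),
         p.value = stats::setNames(pval, names(est)),
         df.residual = df, sigma2 = sigma2, nobs = n),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit> n =", x$nobs, " df =", x$df.residual, "\n")
  print(as.data.frame(tidy(x)), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p.value)
  )
}

#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, df.residual = x$df.residual,
                 nobs = x$nobs)
}

#' The two competing analysis models
#'
#' `fit_unadjusted()` regresses depression symptoms on the inflammatory
#' protein alone; `fit_adjusted()` adds adiposity as a second predictor. The
#' focal coefficient is the inflammation slope in both. When adiposity is an
#' exposure-only ancestor (null direct path), both are unbiased for the
#' inflammation -> depression effect but the adjusted model pays a precision
#' penalty.
#'
#' @param data A data frame with columns `inflammation` and `depression`
#'   (plus `adiposity` for the adjusted model), e.g. from
#'   [simulate_dataset()].
#' @return An `ols_fit`; the row of interest in `tidy()` is
#'   `term == "inflammation"`.
#' @export
fit_unadjusted <- function(data) {
  require_columns(data, c("inflammation", "depression"))
  fit_ols(data$depression, cbind(inflammation = data$inflammation))
}

#' @rdname fit_unadjusted
#' @export
fit_adjusted <- function(data) {
  require_columns(data, c("inflammation", "depression", "adiposity"))
  fit_ols(data$depression,
          cbind(inflammation = data$inflammation,
                adiposity = data$adiposity))
}

focal_row <- function(fit, term = "inflammation") {
  i <- match(term, names(fit$coefficients))
  list(estimate = unname(fit$coefficients[i]), se = unname(fit$se[i]),
       p = unname(fit$p.value[i]))
}

require_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("data lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(data)
}
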