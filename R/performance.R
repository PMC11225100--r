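#' Summarize Monte Carlo performance per scenario and method
#'
#' Simsum-style performance measures with Monte Carlo standard errors
#' (MCSEs), computed per `(scenario_label, method)` cell:
#'
#' * `bias` = mean(estimate) - true value;
#' * `empse` = sample SD of the estimates (the empirical SE), with
#'   `empse_mcse = empse / sqrt(2 (n_reps - 1))`;
#' * `modse` = sqrt(mean(se^2)), the root mean squared model-reported SE;
#' * `power` = share of replications with `p < alpha`, with the binomial
#'   MCSE; replications with a missing p-value are excluded with a message;
#' * `precision_gain_pct` = `100 * ((empse_ref / empse)^2 - 1)` relative to
#'   the reference method -- negative values mean the method is *less*
#'   precise than the reference; exactly 0 for the reference itself. Its
#'   MCSE is a leave-one-replication-out jackknife over the paired estimate
#'   streams, which respects the correlation induced by fitting both methods
#'   to the same datasets.
#'
#' @param results A per-replication results tibble from [run_scenario()] or
#'   [run_study()].
#' @param true_value The generating value of the focal coefficient: a single
#'   number, or a named vector keyed by `scenario_label` (see
#'   [true_values()]).
#' @param ref_method Reference method for the precision comparison (default
#'   `"unadjusted"`).
#' @param alpha Two-sided significance level for power (default 0.05).
#' @return A tibble with one row per scenario x method: `scenario_label`,
#'   `method`, `n`, `n_reps`, `mean_estimate`, `bias`, `empse`,
#'   `empse_mcse`, `modse`, `power`, `power_mcse`, `precision_gain_pct`,
#'   `precision_gain_mcse`.
#' @export
summarize_performance <- function(results, true_value,
                                  ref_method = "unadjusted", alpha = 0.05) {
  require_columns(results, c("scenario_label", "n", "rep", "method",
                             "estimate", "se", "p"))
  if (!ref_method %in% results$method) {
    stop("reference method `", ref_method, "` not present in results",
         call. = FALSE)
  }
  labels <- unique(results$scenario_label)
  if (is.null(names(true_value))) {
    if (length(true_value) != 1L) {
      stop("`true_value` must be a scalar or named by scenario label",
           call. = FALSE)
    }
    true_value <- stats::setNames(rep(true_value, length(labels)), labels)
  }
  missing_tv <- setdiff(labels, names(true_value))
  if (length(missing_tv)) {
    stop("no true value supplied for scenario(s): ",
         paste(missing_tv, collapse = ", "), call. = FALSE)
  }

  n_bad_p <- sum(is.na(results$p))
  if (n_bad_p > 0) {
    message(n_bad_p, " replication(s) with missing p-values excluded from power")
  }

  cells <- results |>
    dplyr::group_by(.data$scenario_label, .data$method) |>
    dplyr::summarise(
      n = .data$n[1],
      n_reps = dplyr::n(),
      mean_estimate = mean(.data$estimate),
      empse = stats::sd(.data$estimate),
      modse = sqrt(mean(.data$se^2)),
      power = mean(.data$p[!is.na(.data$p)] < alpha),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bias = .data$mean_estimate - unname(true_value[.data$scenario_label]),
      empse_mcse = .data$empse / sqrt(2 * (.data$n_reps - 1)),
      power_mcse = sqrt(.data$power * (1 - .data$power) / .data$n_reps)
    )
  if (any(cells$n_reps < 2L)) {
    stop("need at least 2 replications per method", call. = FALSE)
  }
  if (any(cells$empse == 0)) {
    bad <- cells[cells$empse == 0, ]
    stop("degenerate (zero) empirical SE for ", bad$scenario_label[1], "/",
         bad$method[1], "; precision ratios are undefined", call. = FALSE)
  }

  gains <- purrr::map_dfr(labels, function(lab) {
    sub <- results[results$scenario_label == lab, ]
    methods <- unique(sub$method)
    ref <- sub[sub$method == ref_method, ]
    ref <- ref[order(ref$rep), ]
    purrr::map_dfr(methods, function(meth) {
      if (meth == ref_method) {
        return(tibble::tibble(scenario_label = lab, method = meth,
                              precision_gain_pct = 0,
                              precision_gain_mcse = 0))
      }
      oth <- sub[sub$method == meth, ]
      oth <- oth[order(oth$rep), ]
      common <- intersect(ref$rep, oth$rep)
      er <- ref$estimate[match(common, ref$rep)]
      eo <- oth$estimate[match(common, oth$rep)]
      jk <- jackknife_precision_gain(er, eo)
      tibble::tibble(scenario_label = lab, method = meth,
                     precision_gain_pct = jk$gain,
                     precision_gain_mcse = jk$mcse)
    })
  })

  cells |>
    dplyr::left_join(gains, by = c("scenario_label", "method")) |>
    dplyr::mutate(alpha = alpha, ref_method = ref_method) |>
    dplyr::select("scenario_label", "method", "n", "n_reps",
                  "mean_estimate", "bias", "empse", "empse_mcse", "modse",
                  "power", "power_mcse", "precision_gain_pct",
                  "precision_gain_mcse", "alpha", "ref_method") |>
    dplyr::arrange(.data$scenario_label, .data$method != ref_method)
}

# precision gain of `other` vs `ref` with leave-one-replication-out jackknife
# MCSE; the two estimate streams are paired by replication
jackknife_precision_gain <- function(est_ref, est_other) {
  r <- length(est_ref)
  stopifnot(r == length(est_other), r >= 2L)
  gain_of <- function(vr, vo) 100 * (vr / vo - 1)
  vr <- stats::var(est_ref)
  vo <- stats::var(est_other)
  if (vo == 0 || vr == 0) {
    stop("degenerate (zero) empirical SE; precision ratio undefined",
         call. = FALSE)
  }
  gain <- gain_of(vr, vo)
  if (r == 2L) return(list(gain = gain, mcse = NA_real_))
  # leave-one-out variance identity: SS_{-i} = SS - n/(n-1) (x_i - xbar)^2
  loo_var <- function(x) {
    ss <- (length(x) - 1) * stats::var(x)
    (ss - length(x) / (length(x) - 1) * (x - mean(x))^2) / (length(x) - 2)
  }
  g_i <- gain_of(loo_var(est_ref), loo_var(est_other))
  mcse <- sqrt((r - 1) / r * sum((g_i - mean(g_i))^2))
  list(gain = gain, mcse = mcse)
}

#' Paired comparison of reported standard errors between methods
#'
#' For each scenario and each non-reference method, a paired t test over the
#' per-replication differences `d_r = se_ref,r - se_other,r`. Negative t
#' means the non-reference method's reported SEs are systematically larger.
#'
#' @inheritParams summarize_performance
#' @return A tibble with columns `scenario_label`, `method`, `t`, `df`,
#'   `p.value`, `mean_diff`.
#' @export
compare_se_paired <- function(results, ref_method = "unadjusted") {
  require_columns(results, c("scenario_label", "rep", "method", "se"))
  if (!ref_method %in% results$method) {
    stop("reference method `", ref_method, "` not present in results",
         call. = FALSE)
  }
  labels <- unique(results$scenario_label)
  purrr::map_dfr(labels, function(lab) {
    sub <- results[results$scenario_label == lab, ]
    ref <- sub[sub$method == ref_method, ]
    purrr::map_dfr(setdiff(unique(sub$method), ref_method), function(meth) {
      oth <- sub[sub$method == meth, ]
      common <- intersect(ref$rep, oth$rep)
      if (length(common) < 2L) {
        stop("need at least 2 paired replications", call. = FALSE)
      }
      d <- ref$se[match(common, ref$rep)] - oth$se[match(common, oth$rep)]
      sdd <- stats::sd(d)
      if (sdd == 0) {
        stop("all paired SE differences are identical in scenario `", lab,
             "`; the paired t statistic is undefined", call. = FALSE)
      }
      tstat <- mean(d) / (sdd / sqrt(length(d)))
      df <- length(d) - 1L
      tibble::tibble(scenario_label = lab, method = meth, t = tstat,
                     df = df,
                     p.value = 2 * stats::pt(abs(tstat), df,
                                             lower.tail = FALSE),
                     mean_diff = mean(d))
    })
  })
}

#' Closed-form large-sample precision loss from adjusting for the ancestor
#'
#' When the direct path is null, adding the exposure's ancestor (path
#' coefficient `a` into the exposure) to the outcome model inflates the
#' sampling variance of the focal coefficient by `1 / (1 - R2)` where `R2`
#' is the share of exposure variance the ancestor explains. The implied
#' percentage precision loss in the limit of many replications is
#' `100 * a^2` under the standardized convention (exposure variance 1) and
#' `100 * a^2 / (1 + a^2)` under unit residual variances (exposure variance
#' `1 + a^2`).
#'
#' @param a Ancestor -> exposure path coefficient.
#' @param convention `"unit_residual"` or `"standardized"`.
#' @return Percentage precision loss (a positive number; compare with the
#'   negative of `precision_gain_pct`).
#' @examples
#' analytic_precision_loss(0.274, "unit_residual")
#' @export
analytic_precision_loss <- function(a, convention = c("unit_residual",
                                                      "standardized")) {
  convention <- match.arg(convention)
  if (convention == "standardized") {
    if (any(abs(a) >= 1)) {
      stop("|a| must be below 1 under the standardized convention",
           call. = FALSE)
    }
    100 * a^2
  } else {
    100 * a^2 / (1 + a^2)
  }
}
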