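#' Dot plot of relative precision gain with MCSE intervals
#'
#' One point per scenario x method at its precision gain relative to the
#' reference method (0% line), with +/- 1.96 MCSE intervals. Negative values
#' mean the method is less precise than the reference.
#'
#' @param summary A performance summary from [summarize_performance()].
#' @return A ggplot object.
#' @export
plot_precision_gain <- function(summary) {
  require_columns(summary, c("scenario_label", "method",
                             "precision_gain_pct", "precision_gain_mcse"))
  ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$precision_gain_pct, y = .data$scenario_label,
                 colour = .data$method)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$precision_gain_pct -
                     1.96 * .data$precision_gain_mcse,
                   xmax = .data$precision_gain_pct +
                     1.96 * .data$precision_gain_mcse),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Relative precision gain vs reference (%)",
                  y = NULL, colour = "Method") +
    ggplot2::theme_minimal()
}

#' Overlaid densities of reported standard errors per method
#'
#' @param results Per-replication results from [run_scenario()] or
#'   [run_study()].
#' @return A ggplot object, faceted by scenario.
#' @export
plot_se_distributions <- function(results) {
  require_columns(results, c("scenario_label", "method", "se"))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$se, fill = .data$method)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::facet_wrap(~scenario_label, scales = "free") +
    ggplot2::labs(x = "Reported standard error of the focal coefficient",
                  y = "Density", fill = "Method") +
    ggplot2::theme_minimal()
}
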