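# ggplot2 views of MR results.

#' Forest plot of MR estimates
#'
#' @param estimates An estimate tibble as found in `mr_report$estimates`
#'   (columns `method`, `odds_ratio`, `ci_low`, `ci_high`, and optionally
#'   `exposure` / `outcome` for faceting).
#' @return A ggplot object (odds ratios on a log axis).
#' @export
plot_forest <- function(estimates) {
  assert_columns(estimates, c("method", "odds_ratio", "ci_low", "ci_high"),
                 "`estimates`")
  p <- ggplot2::ggplot(
    estimates,
    ggplot2::aes(x = .data$odds_ratio, y = .data$method)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (all(c("exposure", "outcome") %in% names(estimates))) {
    p <- p + ggplot2::facet_grid(exposure ~ outcome)
  }
  p
}

#' @method autoplot mr_report
#' @export
autoplot.mr_report <- function(object, ...) plot_forest(object$estimates)

#' Leave-one-out forest plot
#'
#' @param object An `"mr_loo"` tibble from [mr_leave_one_out()].
#' @param ... Unused.
#' @return A ggplot object; the dashed line marks the full-set IVW
#'   estimate.
#' @method autoplot mr_loo
#' @export
autoplot.mr_loo <- function(object, ...) {
  full <- attr(object, "full_estimate")
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$odds_ratio,
                 y = stats::reorder(.data$variant_id, .data$odds_ratio))
  ) +
    ggplot2::geom_vline(xintercept = exp(full$beta), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0
    ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "Odds ratio omitting variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' Mediated-proportion plot
#'
#' @param mediation_table The `mediation_table` tibble of an `mr_report`
#'   (or any tibble with `mediator`, `outcome`, `proportion_pct`,
#'   `ci_low_pct`, `ci_high_pct`).
#' @return A ggplot object.
#' @export
plot_mediation <- function(mediation_table) {
  assert_columns(mediation_table,
                 c("mediator", "outcome", "proportion_pct",
                   "ci_low_pct", "ci_high_pct"), "`mediation_table`")
  ggplot2::ggplot(
    mediation_table,
    ggplot2::aes(x = .data$outcome, y = .data$proportion_pct,
                 fill = .data$mediator)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low_pct, ymax = .data$ci_high_pct),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::labs(y = "Proportion mediated (%)", x = NULL) +
    ggplot2::theme_minimal()
}
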