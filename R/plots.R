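# ggplot2 displays for fitted models, lag scans and validation results.

#' Forest plot of adjusted odds ratios
#'
#' @param object A `glmm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glmm_fit <- function(object, ...) {
  df <- report_or(object) |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$or, y = stats::reorder(.data$term, .data$or)
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$or.low, xmax = .data$or.high
    )) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "adjusted odds ratio (95% CI, log scale)", y = NULL,
      title = "Random-intercept logistic regression"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a temporal-lag scan
#'
#' Within-person coefficients (as odds ratios for the forward direction)
#' across feature lags.
#'
#' @param scan Output of [lag_scan()].
#' @return A ggplot.
#' @export
plot_lag_scan <- function(scan) {
  df <- scan |>
    dplyr::filter(grepl("_within$", .data$term))
  forward <- all(df$direction == "forward")
  if (forward) {
    df <- dplyr::mutate(df,
      est = exp(.data$estimate),
      lo = exp(.data$conf.low), hi = exp(.data$conf.high)
    )
  } else {
    df <- dplyr::mutate(df, est = .data$estimate,
      lo = .data$conf.low, hi = .data$conf.high)
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$lag), y = .data$est, colour = .data$term
  )) +
    ggplot2::geom_hline(yintercept = if (forward) 1 else 0,
      linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(
      x = "feature lag (weeks)",
      y = if (forward) "adjusted odds ratio (95% CI)" else "coefficient (95% CI)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot validation AUCs with confidence intervals
#'
#' @param results Rows from [leave_future_out()] and/or [between_person()].
#' @return A ggplot.
#' @export
plot_validation <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(
    x = .data$auc, y = stats::reorder(.data$label, .data$model_id),
    colour = .data$above_chance
  )) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$ci_low, xmax = .data$ci_high
    )) +
    ggplot2::facet_grid(.data$design ~ .data$outcome) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "AUC (95% CI)", y = NULL,
      colour = "lower bound ≥ 0.5") +
    ggplot2::theme_minimal()
}
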