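#' Plot a time--activity curve
#'
#' @param tac A TAC tibble.
#' @param ... Unused.
#' @return A ggplot object (frame-average steps with midpoints).
#' @export
plot_tac <- function(tac, ...) {
  mids <- tac_midpoints(tac)
  df <- dplyr::mutate(tac, mid = mids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$frame_start,
                                       xend = .data$frame_end,
                                       yend = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time post-injection (min)",
                  y = "Activity concentration (kBq/mL)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Patlak plot of a fitted lesion
#'
#' Shows the transform points with the fitted regression line; the slope
#' (x 100) is the reported Ki.
#'
#' @param object A `patlak_fit`.
#' @param ... Unused.
#' @export
autoplot.patlak_fit <- function(object, ...) {
  pts <- object$points_used
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$Ki / 100,
                         intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "Normalized time  ∫Cp/Cp (min)",
      y = "Ct / Cp",
      title = sprintf("Patlak fit: Ki = %.2f mL/min/100 mL",
                      object$Ki)
    ) +
    ggplot2::theme_minimal()
}

#' Bland--Altman plot of test--retest percent differences
#'
#' One panel per metric: percent difference against the pair mean, with the
#' mean (solid) and mean +/- 2 SD limits of repeatability (dashed).
#'
#' @param ba_data The `bland_altman` table from [run_report()], optionally
#'   pre-filtered by tracer/metric.
#' @param metrics Metrics to include (default all present).
#' @export
plot_bland_altman <- function(ba_data, metrics = unique(ba_data$metric)) {
  df <- ba_data[ba_data$metric %in% metrics, ]
  lims <- dplyr::summarise(
    dplyr::group_by(df, .data$metric),
    mu = mean(.data$pct_delta), sigma = stats::sd(.data$pct_delta),
    .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_mean,
                                   y = .data$pct_delta)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = .data$mu),
                        color = "orange") +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$mu - 2 * .data$sigma),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$mu + 2 * .data$sigma),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "Pair mean", y = "Test-retest %Δ") +
    ggplot2::theme_minimal()
}

#' Box plots of test--retest percent-difference distributions
#'
#' @param box_data The `boxplot_data` table from [run_report()].
#' @param absolute Plot `|%delta|` instead of signed `%delta`.
#' @export
plot_pct_delta_box <- function(box_data, absolute = FALSE) {
  yvar <- if (absolute) "abs_pct_delta" else "pct_delta"
  ggplot2::ggplot(box_data,
                  ggplot2::aes(x = .data$metric, y = .data[[yvar]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL,
                  y = if (absolute) "Test-retest |%Δ|"
                      else "Test-retest %Δ") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
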