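# ggplot2 displays for simulated traces and calibration fits.

#' Plot a simulated MRM chromatogram
#'
#' @param trace tibble from [simulate_trace()].
#' @param peak_window optional length-2 time interval to shade.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, peak_window = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(peak_window)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = peak_window[1], xmax = peak_window[2],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}

#' Autoplot a calibration fit
#'
#' Calibration points with the fitted amount-to-intensity line.
#'
#' @param object an `mrm_calibration` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mrm_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$amount, y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "amount (mol)", y = "apex intensity (a.u.)",
      subtitle = sprintf("R² = %.4f", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a diagnostic report
#'
#' Dot-and-interval display of the proportion statistics (percent scale)
#' from [diagnostic_report()]; likelihood ratios are omitted (different
#' scale).
#'
#' @param report tibble from [diagnostic_report()].
#' @return A ggplot object.
#' @export
plot_diagnostic_report <- function(report) {
  pct <- dplyr::filter(report, .data$ci_method != "simel_log",
                       !is.na(.data$estimate))
  ggplot2::ggplot(
    pct,
    ggplot2::aes(x = .data$estimate,
                 y = stats::reorder(.data$statistic, .data$estimate))
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)
    ) +
    ggplot2::labs(x = "estimate (%) with 95% CI", y = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}
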