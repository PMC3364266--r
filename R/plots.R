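#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col labs scale_x_log10 facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a flow waveform
#'
#' @param object A [flow_waveform()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_waveform
#' @export
autoplot.flow_waveform <- function(object, ...) {
  unit <- if (amp_norm_state(object) == "none") "flow (mL/s)" else "flow (normalized)"
  ggplot(object, aes(x = .data$time_ms, y = .data$flow)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "time from R-wave (ms)", y = unit,
         title = sprintf("%s flow", compartment(object))) +
    theme_minimal()
}

#' Plot a harmonic spectrum
#'
#' @param object A `flow_spectrum` from [dft_components()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_spectrum
#' @export
autoplot.flow_spectrum <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$freq_hz), y = .data$magnitude)) +
    geom_col() +
    labs(x = "frequency component (Hz)", y = "magnitude",
         title = sprintf("%s harmonic content", attr(object, "compartment"))) +
    theme_minimal()
}

#' Plot a Bode curve
#'
#' Gain and phase of an identified transfer function versus frequency (log
#' frequency axis, as conventional).
#'
#' @param object A `bode_curve` from [bode()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bode_curve
#' @export
autoplot.bode_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("gain", "phase"),
                              names_to = "panel", values_to = "value")
  ggplot(long, aes(x = .data$freq_hz, y = .data$value)) +
    geom_line() +
    geom_hline(data = data.frame(panel = "gain", y = 1),
               aes(yintercept = .data$y), linetype = 2) +
    scale_x_log10() +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "frequency (Hz)", y = NULL, title = "transfer function") +
    theme_minimal()
}

#' Plot a circular cross-correlogram
#'
#' @param object An `xcorr_result` from [cross_correlate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xcorr_result
#' @export
autoplot.xcorr_result <- function(object, ...) {
  ggplot(object, aes(x = .data$lag_ms, y = .data$r)) +
    geom_line() +
    geom_point(data = object[which.max(object$r), ], colour = "red") +
    labs(x = "lag (ms)", y = "normalized correlation",
         title = sprintf("circular cross-correlation (peak %.0f ms)",
                         attr(object, "delay_ms"))) +
    theme_minimal()
}

#' Plot detected feature points over the waveform fit
#'
#' @param points A `feature_points` tibble from [detect_feature_points()].
#' @param waveform Optionally, the waveform the points were detected on.
#' @return A ggplot.
#' @export
plot_feature_points <- function(points, waveform = NULL) {
  p <- ggplot(points, aes(x = .data$time_ms, y = .data$amplitude))
  if (!is.null(waveform))
    p <- p + geom_line(data = waveform,
                       aes(x = .data$time_ms, y = .data$flow),
                       colour = "grey60")
  fit <- hermite_fit(points, seq(min(points$time_ms), max(points$time_ms), 5))
  p + geom_line(data = fit, linetype = 2) +
    geom_point(colour = "red") +
    labs(x = "time (ms)", y = "flow", title = "waveform feature points") +
    theme_minimal()
}
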