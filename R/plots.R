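#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recording waveform
#'
#' @param object An [audio_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.audio_recording <- function(object, ...) {
  df <- tibble::tibble(
    time_s = (seq_along(object$samples) - 1) / object$rate,
    amplitude = object$samples
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude",
                  title = sprintf("%s (%s, %s)", object$id,
                                  object$sound_kind, object$label)) +
    ggplot2::theme_minimal()
}

#' Plot an amplitude spectrum
#'
#' @param object A `spectrum_summary` from [fft_spectrum()].
#' @param ... Unused.
#' @return A ggplot with the detected bands shaded.
#' @export
autoplot.spectrum_summary <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$magnitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Amplitude",
                  title = sprintf("Spectrum of %s (peak %.3g at %.0f Hz)",
                                  object$id, object$peak_amplitude,
                                  object$peak_freq)) +
    ggplot2::theme_minimal()
  if (nrow(object$bands)) {
    p <- p + ggplot2::geom_rect(
      data = object$bands,
      ggplot2::aes(xmin = .data$low_hz, xmax = .data$high_hz,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.12, fill = "steelblue")
  }
  p
}

#' Plot metrics across the voting threshold sweep
#'
#' Fold-averaged accuracy, sensitivity, specificity, precision and F1
#' against the voting threshold.
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary,
    c("accuracy", "specificity", "sensitivity", "precision", "f1"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "Voting threshold", y = "Metric (fold mean)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
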