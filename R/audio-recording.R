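#' Construct an audio recording
#'
#' The basic signal container used throughout the package: a mono sequence of
#' real amplitudes in WAV full-scale units (\[-1, 1\]) together with its
#' sampling rate, the kind of sound it carries and a diagnostic label.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param sound_kind One of `"heart"`, `"lung"`, `"noise"`.
#' @param label One of `"normal"`, `"abnormal"`, `"unknown"`.
#' @param id Character identifier for the recording.
#'
#' @return An object of class `audio_recording`: a list with elements
#'   `samples`, `rate`, `sound_kind`, `label`, `id`.
#' @export
#'
#' @examples
#' rec <- audio_recording(sin(2 * pi * 5 * seq(0, 1, by = 1 / 500)), 500)
#' rec
audio_recording <- function(samples, rate,
                            sound_kind = c("heart", "lung", "noise"),
                            label = c("unknown", "normal", "abnormal"),
                            id = "rec") {
  sound_kind <- match.arg(sound_kind)
  label <- match.arg(label)
  if (!is.numeric(samples)) {
    rlang::abort("`samples` must be numeric.", class = "cpsound_argument_error")
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    rlang::abort("`rate` must be a single positive number (Hz).",
                 class = "cpsound_argument_error")
  }
  if (length(samples) && any(!is.finite(samples))) {
    rlang::abort("All amplitudes must be finite.", class = "cpsound_argument_error")
  }
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         sound_kind = sound_kind, label = label, id = as.character(id)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> id=%s kind=%s label=%s\n", x$id, x$sound_kind, x$label))
  cat(sprintf("  %d samples @ %g Hz (%.3f s), peak |amp| %.4g\n",
              length(x$samples), x$rate,
              length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio_recording <- function(x) length(x$samples)

#' Duration of a recording in seconds
#' @param rec An [audio_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  length(rec$samples) / rec$rate
}

check_recording <- function(rec, arg = "rec") {
  if (!inherits(rec, "audio_recording")) {
    rlang::abort(sprintf("`%s` must be an <audio_recording>.", arg),
                 class = "cpsound_argument_error")
  }
  if (!length(rec$samples)) {
    rlang::abort(sprintf("`%s` has no samples.", arg),
                 class = "cpsound_argument_error")
  }
  invisible(rec)
}
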