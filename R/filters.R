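#' Resample a recording to a new rate
#'
#' Polyphase rational resampling (via [signal::resample()]) after reducing
#' `target_rate / rate` to lowest terms. Duration is preserved to within one
#' sample period and band content below the smaller Nyquist frequency is
#' retained.
#'
#' @param rec An [audio_recording()].
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return An [audio_recording()] at `target_rate`.
#' @export
resample_audio <- function(rec, target_rate) {
  check_recording(rec)
  if (!is.numeric(target_rate) || length(target_rate) != 1 || target_rate <= 0) {
    rlang::abort("`target_rate` must be a single positive rate in Hz.",
                 class = "cpsound_argument_error")
  }
  if (isTRUE(all.equal(target_rate, rec$rate))) return(rec)
  pq <- rationalize_ratio(target_rate / rec$rate)
  y <- signal::resample(rec$samples, pq[1], pq[2])
  n_out <- round(length(rec$samples) * target_rate / rec$rate)
  y <- fit_length(y, n_out)
  audio_recording(y, target_rate, sound_kind = rec$sound_kind,
                  label = rec$label, id = rec$id)
}

# smallest p/q within 1e-6 of r (continued fractions)
rationalize_ratio <- function(r, tol = 1e-6, max_den = 10000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < tol * r) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(as.integer(p1), as.integer(q1))
}

fit_length <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, rep(0, n - length(x)))
}

butter_band <- function(rec, w, type, min_rate, band_name) {
  check_recording(rec)
  if (rec$rate <= min_rate) {
    rlang::abort(sprintf(
      "Sampling rate %g Hz is too low for the %s filter (need > %g Hz).",
      rec$rate, band_name, min_rate), class = "cpsound_precondition_error")
  }
  filt <- signal::butter(4, w / (rec$rate / 2), type = type)
  y <- signal::filtfilt(filt, rec$samples)
  audio_recording(y, rec$rate, sound_kind = rec$sound_kind,
                  label = rec$label, id = rec$id)
}

#' Heart-band filter (low-pass at 400 Hz)
#'
#' Digital counterpart of the heart-sound conditioning chain: a 4th-order
#' Butterworth low-pass at 400 Hz applied forward and backward, so the
#' passband gain is ~1 and no phase distortion is introduced into the S1/S2
#' transients.
#'
#' @param rec An [audio_recording()] with `rate > 800` Hz.
#' @return The filtered recording.
#' @export
heart_filter <- function(rec) {
  butter_band(rec, 400, "low", 800, "heart")
}

#' Lung-band filter (band-pass 100--2000 Hz)
#'
#' 4th-order Butterworth band-pass between 100 Hz and 2000 Hz, applied
#' forward-backward (zero phase).
#'
#' @param rec An [audio_recording()] with `rate > 4000` Hz.
#' @return The filtered recording.
#' @export
lung_filter <- function(rec) {
  butter_band(rec, c(100, 2000), "pass", 4000, "lung")
}
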