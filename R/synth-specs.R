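# Parameter records for the synthetic heart / lung generators. Ranges follow
# the physiology the segmentation grid was designed around: heartbeats at
# 50-80 per minute and respiration at 12-20 per minute.

#' Heart sound specification
#'
#' @param bpm Heart rate in beats per minute, within \[50, 80\].
#' @param duration_s Recording length in seconds (> 0).
#' @param murmur_amp Relative amplitude of the systolic murmur noise burst;
#'   0 produces a normal recording, > 0 an abnormal one.
#' @param murmur_band Two-element `c(low, high)` murmur band in Hz.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed; the generated waveform is a deterministic
#'   function of the spec.
#' @return A list of class `heart_spec`.
#' @export
heart_spec <- function(bpm = 60, duration_s = 10, murmur_amp = 0,
                       murmur_band = c(150, 400), rate = 2000, seed = 1) {
  if (!is.numeric(bpm) || bpm < 50 || bpm > 80) {
    rlang::abort("`bpm` must lie in [50, 80].", class = "cpsound_argument_error")
  }
  if (duration_s <= 0) {
    rlang::abort("`duration_s` must be positive.", class = "cpsound_argument_error")
  }
  if (murmur_amp < 0) {
    rlang::abort("`murmur_amp` must be >= 0.", class = "cpsound_argument_error")
  }
  structure(list(bpm = bpm, duration_s = duration_s, murmur_amp = murmur_amp,
                 murmur_band = murmur_band, rate = rate,
                 seed = as.integer(seed)),
            class = "heart_spec")
}

#' Lung sound specification
#'
#' @param breaths_per_min Respiration rate in breaths per minute, within
#'   \[12, 20\].
#' @param duration_s Recording length in seconds (> 0).
#' @param wheeze_amp Relative amplitude of the expiratory wheeze tone (>= 0).
#' @param wheeze_freq Wheeze tone frequency in Hz.
#' @param crackle_rate Crackle transients per second (>= 0).
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A list of class `lung_spec`. The recording is abnormal iff
#'   `wheeze_amp > 0` or `crackle_rate > 0`.
#' @export
lung_spec <- function(breaths_per_min = 15, duration_s = 20, wheeze_amp = 0,
                      wheeze_freq = 400, crackle_rate = 0, rate = 8000,
                      seed = 1) {
  if (!is.numeric(breaths_per_min) || breaths_per_min < 12 || breaths_per_min > 20) {
    rlang::abort("`breaths_per_min` must lie in [12, 20].",
                 class = "cpsound_argument_error")
  }
  if (duration_s <= 0) {
    rlang::abort("`duration_s` must be positive.", class = "cpsound_argument_error")
  }
  if (wheeze_amp < 0 || crackle_rate < 0) {
    rlang::abort("Abnormality amplitudes must be >= 0.",
                 class = "cpsound_argument_error")
  }
  structure(list(breaths_per_min = breaths_per_min, duration_s = duration_s,
                 wheeze_amp = wheeze_amp, wheeze_freq = wheeze_freq,
                 crackle_rate = crackle_rate, rate = rate,
                 seed = as.integer(seed)),
            class = "lung_spec")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
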