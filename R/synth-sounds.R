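# Seeded generators for synthetic heart and lung recordings. These emulate
# the statistical structure the classifier relies on -- a dominant periodic
# template (S1/S2 transients, breath envelopes) that PCA can strip, plus
# abnormal components (murmur bursts, wheeze tones, crackles) that survive
# in the residual -- without attempting physiologically faithful waveforms.

gauss_tone <- function(t, center, width_s, freq) {
  # Gaussian-windowed tone; width_s is the ~full width (4 sigma)
  sigma <- width_s / 4
  exp(-0.5 * ((t - center) / sigma)^2) * sin(2 * pi * freq * (t - center))
}

band_noise <- function(n, rate, low, high, order = 4) {
  x <- stats::rnorm(n)
  w <- c(low, high) / (rate / 2)
  if (w[2] >= 1) w[2] <- 0.999
  filt <- signal::butter(order, w, type = "pass")
  as.numeric(signal::filtfilt(filt, x))
}

#' Generate a synthetic heart sound
#'
#' Each cardiac cycle (period `60/bpm` s) carries an S1 transient (a
#' Gaussian-windowed 40 Hz tone of ~60 ms) at the cycle start and an S2
#' transient (60 Hz, ~40 ms) at 35% of the cycle (end of systole). When
#' `murmur_amp > 0`, band-limited noise bursts fill systole and the recording
#' is labelled abnormal. A low-level white noise floor is always present.
#' The waveform is peak-normalized to 0.9 and is a deterministic function of
#' the spec (including its seed).
#'
#' @param spec A [heart_spec()].
#' @return An [audio_recording()] with an `events` attribute: a tibble of S1
#'   and S2 onset times.
#' @export
generate_heart <- function(spec) {
  if (!inherits(spec, "heart_spec")) {
    rlang::abort("`spec` must be a <heart_spec>.", class = "cpsound_argument_error")
  }
  rate <- spec$rate
  n <- round(spec$duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  period <- 60 / spec$bpm
  n_cycles <- floor(spec$bpm * spec$duration_s / 60)
  s1_times <- (seq_len(n_cycles) - 1) * period
  s2_times <- s1_times + 0.35 * period

  x <- numeric(n)
  for (k in seq_len(n_cycles)) {
    x <- x + gauss_tone(t, s1_times[k] + 0.03, 0.060, 40)
    x <- x + 0.8 * gauss_tone(t, s2_times[k] + 0.02, 0.040, 60)
  }

  x <- x + with_seed(spec$seed, {
    extra <- numeric(n)
    if (spec$murmur_amp > 0) {
      murmur <- band_noise(n, rate, spec$murmur_band[1], spec$murmur_band[2])
      murmur <- murmur / stats::sd(murmur)
      env <- numeric(n)
      for (k in seq_len(n_cycles)) {
        lo <- s1_times[k] + 0.07
        hi <- s2_times[k]
        env <- env + exp(-0.5 * ((t - (lo + hi) / 2) / ((hi - lo) / 4))^2)
      }
      extra <- extra + spec$murmur_amp * 0.35 * murmur * env
    }
    extra + 0.002 * stats::rnorm(n)
  })

  x <- 0.9 * x / max(abs(x))
  rec <- audio_recording(
    x, rate, sound_kind = "heart",
    label = if (spec$murmur_amp > 0) "abnormal" else "normal",
    id = sprintf("heart_%d", spec$seed)
  )
  attr(rec, "events") <- tibble::tibble(
    type = rep(c("S1", "S2"), each = n_cycles),
    time_s = c(s1_times, s2_times)
  )
  attr(rec, "spec") <- spec
  rec
}

#' Generate a synthetic lung sound
#'
#' Breath sounds are modelled as broadband noise (band-passed to the
#' 100--2000 Hz lung band) amplitude-modulated by one `sin^2` envelope per
#' breath. A wheeze adds a tone at `wheeze_freq` during expiration (the
#' second half of each breath cycle); crackles add brief damped transients at
#' seeded random times. The recording is abnormal iff `wheeze_amp > 0` or
#' `crackle_rate > 0`. Peak-normalized to 0.9; deterministic given the spec.
#'
#' @param spec A [lung_spec()].
#' @return An [audio_recording()] with an `events` attribute giving breath
#'   envelope peak times.
#' @export
generate_lung <- function(spec) {
  if (!inherits(spec, "lung_spec")) {
    rlang::abort("`spec` must be a <lung_spec>.", class = "cpsound_argument_error")
  }
  rate <- spec$rate
  n <- round(spec$duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  period <- 60 / spec$breaths_per_min
  n_breaths <- floor(spec$breaths_per_min * spec$duration_s / 60)

  # one sin^2 arch per complete breath; silence after the last complete breath
  phase <- t / period
  env <- ifelse(phase < n_breaths, sin(pi * (phase %% 1))^2, 0)

  x <- with_seed(spec$seed, {
    base <- band_noise(n, rate, 100, 2000)
    base <- base / stats::sd(base)
    sig <- base * (0.15 + env)

    if (spec$wheeze_amp > 0) {
      expir <- as.numeric((phase %% 1) >= 0.5 & phase < n_breaths)
      sig <- sig + spec$wheeze_amp * 3 * expir * env *
        sin(2 * pi * spec$wheeze_freq * t)
    }
    if (spec$crackle_rate > 0) {
      n_crackles <- max(1L, round(spec$crackle_rate * spec$duration_s))
      at <- sort(stats::runif(n_crackles, 0, spec$duration_s - 0.01))
      for (a in at) {
        idx <- which(t >= a & t < a + 0.006)
        sig[idx] <- sig[idx] + 2.5 * exp(-(t[idx] - a) * 800) *
          sin(2 * pi * 650 * (t[idx] - a))
      }
    }
    sig
  })

  x <- 0.9 * x / max(abs(x))
  abnormal <- spec$wheeze_amp > 0 || spec$crackle_rate > 0
  rec <- audio_recording(
    x, rate, sound_kind = "lung",
    label = if (abnormal) "abnormal" else "normal",
    id = sprintf("lung_%d", spec$seed)
  )
  attr(rec, "events") <- tibble::tibble(
    type = "breath_peak",
    time_s = ((seq_len(n_breaths)) - 0.5) * period
  )
  attr(rec, "spec") <- spec
  rec
}
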