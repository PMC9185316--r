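# Two-channel noise mixtures emulating the dual-microphone architecture:
# one channel hears the body sound plus coupled environmental noise, the
# other hears the noise alone (possibly gained, delayed or spectrally
# shifted by the propagation medium). Ward-construction and airport noise
# stand-ins are band-shaped white noise processes (150-450 Hz and
# 100-600 Hz), matching the measured bands of those sources.

#' Coupling description for a two-channel noise mixture
#'
#' @param gain Multiplicative gain applied to the reference channel.
#' @param delay_s Delay of the reference channel in seconds.
#' @param freq_shift Multiplicative frequency shift (1 = none). Values
#'   above 1 model a medium that raises the apparent noise pitch (e.g. a
#'   ~300 Hz peak heard at ~325 Hz corresponds to 1.08).
#' @return A list of class `noise_coupling`.
#' @export
noise_coupling <- function(gain = 1, delay_s = 0, freq_shift = 1) {
  structure(list(gain = gain, delay_s = delay_s, freq_shift = freq_shift),
            class = "noise_coupling")
}

noise_process <- function(n, rate, kind) {
  switch(kind,
    ward    = band_noise(n, rate, 150, min(450, 0.49 * rate)),
    airport = band_noise(n, rate, 100, min(600, 0.49 * rate)),
    white   = stats::rnorm(n),
    rlang::abort(sprintf("Unknown noise kind: %s", kind),
                 class = "cpsound_argument_error")
  )
}

apply_coupling <- function(x, rate, coupling) {
  y <- x
  if (!isTRUE(all.equal(coupling$freq_shift, 1))) {
    # time-compress by the shift factor so frequencies scale multiplicatively
    pq <- rationalize_ratio(1 / coupling$freq_shift)
    y <- as.numeric(signal::resample(y, pq[1], pq[2]))
    y <- fit_length(y, length(x))
  }
  d <- round(coupling$delay_s * rate)
  if (d > 0) y <- c(rep(0, d), y)[seq_along(x)]
  coupling$gain * y
}

#' Mix a clean recording with a coupled noise process
#'
#' The primary channel is `clean + noise`, with the noise scaled so the
#' clean-to-noise power ratio equals `snr_db`. The reference channel is the
#' same noise process transformed by `coupling`; with identity coupling,
#' subtracting the reference from the primary recovers the clean signal
#' exactly.
#'
#' @param clean An [audio_recording()].
#' @param noise_kind One of `"ward"`, `"airport"`, `"white"`.
#' @param snr_db Signal-to-noise ratio in dB (finite).
#' @param coupling A [noise_coupling()].
#' @param seed Integer seed for the noise process.
#' @return A list of class `noise_mixture` with elements `primary`,
#'   `reference`, `clean` (all [audio_recording()]s of equal rate and
#'   length), `snr_db`, `coupling`, `noise_kind`, `seed`.
#' @export
mix_with_noise <- function(clean, noise_kind = c("ward", "airport", "white"),
                           snr_db = 0, coupling = noise_coupling(), seed = 1) {
  check_recording(clean, "clean")
  noise_kind <- match.arg(noise_kind)
  if (!is.finite(snr_db)) {
    rlang::abort("`snr_db` must be finite.", class = "cpsound_argument_error")
  }
  n <- length(clean$samples)
  noise <- with_seed(seed, noise_process(n, clean$rate, noise_kind))
  p_clean <- mean(clean$samples^2)
  p_noise <- mean(noise^2)
  noise <- noise * sqrt(p_clean / (p_noise * 10^(snr_db / 10)))

  primary <- audio_recording(clean$samples + noise, clean$rate,
                             sound_kind = clean$sound_kind,
                             label = clean$label,
                             id = paste0(clean$id, "_noisy"))
  reference <- audio_recording(apply_coupling(noise, clean$rate, coupling),
                               clean$rate, sound_kind = "noise",
                               label = "unknown",
                               id = paste0(clean$id, "_ref"))
  structure(list(primary = primary, reference = reference, clean = clean,
                 snr_db = snr_db, coupling = coupling,
                 noise_kind = noise_kind, seed = as.integer(seed)),
            class = "noise_mixture")
}

#' Generate a labeled synthetic corpus
#'
#' Draws per-recording physiologic parameters uniformly from their stated
#' ranges (heart rate 50--80 bpm, respiration 12--20 breaths/min) under a
#' single corpus seed, so the corpus is reproducible as a whole.
#'
#' @param n_normal,n_abnormal Recording counts per label (>= 0).
#' @param kind `"heart"` or `"lung"`.
#' @param seed Integer corpus seed.
#' @param duration_range Two-element range of recording lengths in seconds.
#'   Defaults: 10--15 s (heart), 15--25 s (lung).
#' @param murmur_amp Murmur amplitude for abnormal heart recordings; a
#'   single value or a range to draw from. Default `c(0.3, 0.7)`.
#' @param wheeze_amp,crackle_rate Abnormal lung parameters; single values or
#'   ranges. Defaults `c(0.3, 0.6)` and `c(0.5, 2)`.
#' @return A tibble with columns `id`, `kind`, `label`, `seed`, the drawn
#'   spec parameters, and a `recording` list-column of [audio_recording()]s.
#' @export
generate_dataset <- function(n_normal, n_abnormal, kind = c("heart", "lung"),
                             seed = 1, duration_range = NULL,
                             murmur_amp = c(0.3, 0.7),
                             wheeze_amp = c(0.3, 0.6),
                             crackle_rate = c(0.5, 2)) {
  kind <- match.arg(kind)
  if (n_normal < 0 || n_abnormal < 0) {
    rlang::abort("Counts must be >= 0.", class = "cpsound_argument_error")
  }
  n <- n_normal + n_abnormal
  if (n == 0) return(tibble::tibble())
  if (is.null(duration_range)) {
    duration_range <- if (kind == "heart") c(10, 15) else c(15, 25)
  }
  draw <- function(rng) if (length(rng) == 1) rep(rng, n) else stats::runif(n, rng[1], rng[2])

  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  params <- with_seed(seed, {
    p <- tibble::tibble(
      label = labels,
      duration_s = draw(duration_range),
      spec_seed = sample.int(.Machine$integer.max %/% 2, n)
    )
    if (kind == "heart") {
      p$bpm <- draw(c(50, 80))
      p$murmur_amp <- ifelse(p$label == "abnormal", draw(murmur_amp), 0)
    } else {
      p$breaths_per_min <- draw(c(12, 20))
      p$wheeze_amp <- ifelse(p$label == "abnormal", draw(wheeze_amp), 0)
      p$crackle_rate <- ifelse(p$label == "abnormal", draw(crackle_rate), 0)
      p$wheeze_freq <- draw(c(200, 600))
    }
    p
  })

  recs <- purrr::pmap(params, function(label, duration_s, spec_seed, ...) {
    dots <- list(...)
    if (kind == "heart") {
      generate_heart(heart_spec(bpm = dots$bpm, duration_s = duration_s,
                                murmur_amp = dots$murmur_amp,
                                seed = spec_seed))
    } else {
      generate_lung(lung_spec(breaths_per_min = dots$breaths_per_min,
                              duration_s = duration_s,
                              wheeze_amp = dots$wheeze_amp,
                              wheeze_freq = dots$wheeze_freq,
                              crackle_rate = dots$crackle_rate,
                              seed = spec_seed))
    }
  })
  ids <- sprintf("%s_%03d", kind, seq_len(n))
  recs <- purrr::map2(recs, ids, function(r, id) { r$id <- id; r })

  dplyr::bind_cols(
    tibble::tibble(id = ids, kind = kind),
    params,
    tibble::tibble(recording = recs)
  )
}

#' Write a corpus to WAV files with a CSV manifest
#'
#' @param corpus A tibble from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; written as `manifest.csv`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(list(corpus$recording, corpus$id), function(rec, id) {
    write_wav(rec, file.path(dir, paste0(id, ".wav")))
  })
  manifest <- dplyr::select(corpus, -"recording")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
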