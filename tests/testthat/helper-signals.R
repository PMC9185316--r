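# Shared fixtures: pure tones, band energy reads, brute-force oracles.

sine_rec <- function(freq, rate, dur_s, amp = 1, kind = "heart") {
  t <- (seq_len(round(dur_s * rate)) - 1) / rate
  audio_recording(amp * sin(2 * pi * freq * t), rate, sound_kind = kind)
}

rms <- function(x) sqrt(mean(x^2))

# total spectral energy in [lo, hi] Hz via the raw FFT
band_energy <- function(samples, rate, lo, hi) {
  p <- Mod(stats::fft(samples))^2
  f <- (seq_along(p) - 1) * rate / length(p)
  sum(p[f >= lo & f <= hi])
}

fft_peak_freq <- function(samples, rate) {
  n <- length(samples)
  p <- Mod(stats::fft(samples))^2
  p <- p[seq_len(floor(n / 2) + 1)]
  (which.max(p) - 1) * rate / n
}

# independent frame-count oracle: enumerate start positions directly
enumerate_frame_count <- function(L, F, overlap) {
  H <- F * (1 - overlap)
  k <- 0
  while (k * H + F <= L + 1e-9) k <- k + 1
  k
}

# exhaustive 1-D weighted-error stump oracle
oracle_stump_error <- function(x, y, w) {
  cand <- sort(unique(x))
  thrs <- c(min(x) - 1, (cand[-1] + cand[-length(cand)]) / 2)
  best <- Inf
  for (thr in thrs) {
    for (pol in c(1, -1)) {
      pred <- ifelse(x > thr, pol, -pol)
      best <- min(best, sum(w[pred != y]))
    }
  }
  best
}

make_separable_2d <- function(n_per_class = 40, margin = 1, seed = 11) {
  set.seed(seed)
  data.frame(
    x1 = c(runif(n_per_class, -3, -margin), runif(n_per_class, margin, 3)),
    x2 = rnorm(2 * n_per_class)
  )
}
separable_labels <- function(n_per_class = 40) {
  rep(c("normal", "abnormal"), each = n_per_class)
}
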