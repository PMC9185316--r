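# The 27-dimensional per-frame feature vector: 11 time-domain statistics,
# 13 Mel-frequency cepstral values, and 3 power-spectrum summaries (16
# frequency-domain features in total). Features are computed on the PCA
# residual, where abnormal components dominate.

stat_feature_names <- c("mean", "std", "mean_abs_dev", "median", "q1", "q3",
                        "iqr", "skewness", "kurtosis", "shannon_entropy",
                        "spectral_entropy")
mfcc_feature_names <- c(sprintf("mfcc_%02d", 1:12), "log_energy")
spectrum_feature_names <- c("power_max", "freq_at_max", "max_energy_fraction")

#' Names of the 27 frame features, in order
#' @return Character vector of length 27.
#' @export
feature_names <- function() {
  c(stat_feature_names, mfcc_feature_names, spectrum_feature_names)
}

one_sided_periodogram <- function(x, rate) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- floor(n / 2) + 1
  p1 <- p[seq_len(k)]
  # double interior bins so the one-sided spectrum carries total power
  if (n >= 3) {
    last_interior <- if (n %% 2 == 0) k - 1 else k
    p1[2:last_interior] <- 2 * p1[2:last_interior]
  }
  list(power = p1, freqs = (seq_len(k) - 1) * rate / n)
}

#' The 11 statistical frame features
#'
#' In order: mean, standard deviation (sample, n-1), mean absolute
#' deviation, median, first quartile, third quartile, interquartile range,
#' skewness (adjusted Fisher--Pearson), kurtosis (Pearson, normal = 3),
#' Shannon entropy, spectral entropy. Quartiles use linear interpolation on
#' the sorted data. Shannon entropy is estimated from a 16-bin equal-width
#' amplitude histogram over the frame's range, in bits. Spectral entropy is
#' the entropy of the periodogram normalized as a probability mass,
#' rescaled by `log2(n_bins)` to \[0, 1\]. Degenerate (zero-variance)
#' frames return 0 for skewness, kurtosis and both entropies.
#'
#' @param samples Numeric vector (length >= 2).
#' @param rate Sampling rate in Hz (only used to define the periodogram).
#' @param entropy_bins Histogram bin count for Shannon entropy (default 16).
#' @return Named numeric vector of length 11.
#' @export
statistical_features <- function(samples, rate = 1, entropy_bins = 16) {
  if (length(samples) < 2) {
    rlang::abort("Need at least 2 samples.", class = "cpsound_argument_error")
  }
  x <- as.numeric(samples)
  n <- length(x)
  mu <- mean(x)
  s <- stats::sd(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)

  if (s > 0) {
    m2 <- mean((x - mu)^2)
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    skew <- sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
    if (n <= 2 || !is.finite(skew)) skew <- 0
    kurt <- m4 / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }

  if (diff(range(x)) > 0) {
    counts <- tabulate(
      pmin(entropy_bins,
           1L + floor(entropy_bins * (x - min(x)) / diff(range(x)))),
      nbins = entropy_bins)
    p <- counts[counts > 0] / n
    h_shannon <- -sum(p * log2(p))
  } else {
    h_shannon <- 0
  }

  pg <- one_sided_periodogram(x, rate)
  tp <- sum(pg$power)
  if (tp > 0 && length(pg$power) > 1) {
    pp <- pg$power[pg$power > 0] / tp
    h_spec <- -sum(pp * log2(pp)) / log2(length(pg$power))
  } else {
    h_spec <- 0
  }

  stats::setNames(
    c(mu, s, mean(abs(x - mu)), q[2], q[1], q[3], q[3] - q[1],
      skew, kurt, h_shannon, h_spec),
    stat_feature_names)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, rate) {
  pts <- mel_to_hz(seq(0, hz_to_mel(rate / 2), length.out = n_filters + 2))
  bin_freqs <- (0:(nfft / 2)) * rate / nfft
  fb <- matrix(0, n_filters, length(bin_freqs))
  for (i in seq_len(n_filters)) {
    lo <- pts[i]; ce <- pts[i + 1]; hi <- pts[i + 2]
    up <- (bin_freqs - lo) / max(ce - lo, 1e-12)
    down <- (hi - bin_freqs) / max(hi - ce, 1e-12)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

dct2_ortho <- function(v, k_max) {
  m <- length(v)
  j <- seq_len(m) - 0.5
  vapply(seq_len(k_max), function(k) {
    sqrt(2 / m) * sum(v * cos(pi * k * j / m))
  }, numeric(1))
}

#' The 13 Mel-frequency cepstral frame features
#'
#' Pre-emphasis (coefficient 0.97), then short-time analysis with 25 ms
#' Hamming sub-windows at a 10 ms hop. For each sub-window: power spectrum
#' (zero-padded FFT), 40 triangular Mel filters spanning 0 to `rate/2`, log
#' filter energies (floored), orthonormal DCT-II; cepstral coefficients
#' 1--12 are averaged across sub-windows. The 13th value is the log of the
#' total frame energy, floored at a small epsilon.
#'
#' @param frame Numeric sample vector, at least one 25 ms sub-window long.
#' @param rate Sampling rate in Hz.
#' @param n_filters Number of Mel filters (default 40).
#' @param n_coeffs Number of cepstral coefficients (default 12).
#' @return Named numeric vector of length `n_coeffs + 1`.
#' @export
mfcc_features <- function(frame, rate, n_filters = 40, n_coeffs = 12) {
  win <- round(0.025 * rate)
  hop <- max(1, round(0.010 * rate))
  if (length(frame) < win) {
    rlang::abort("Frame shorter than one 25 ms analysis sub-window.",
                 class = "cpsound_precondition_error")
  }
  eps <- 1e-12
  x <- as.numeric(frame)
  pre <- c(x[1], x[-1] - 0.97 * x[-length(x)])

  # FFT length large enough that every Mel filter spans at least one bin
  # (empty filters would pin log energies at the floor and break the
  # log-spectrum shift identity under amplitude scaling)
  nfft <- max(256, 2^ceiling(log2(win)))
  fb <- mel_filterbank(n_filters, nfft, rate)
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))

  starts <- seq(1, length(pre) - win + 1, by = hop)
  coef_sum <- numeric(n_coeffs)
  for (s in starts) {
    seg <- pre[s:(s + win - 1)] * ham
    spec <- Mod(stats::fft(c(seg, rep(0, nfft - win))))^2 / nfft
    pow <- spec[1:(nfft / 2 + 1)]
    fe <- log(pmax(as.numeric(fb %*% pow), eps))
    coef_sum <- coef_sum + dct2_ortho(fe, n_coeffs)
  }
  coefs <- coef_sum / length(starts)
  log_e <- log(max(sum(x^2), eps))
  stats::setNames(c(coefs, log_e),
                  c(sprintf("mfcc_%02d", seq_len(n_coeffs)), "log_energy"))
}

#' The 3 power-spectrum frame features
#'
#' Periodogram over the full frame (no tapering, so line components fall in
#' single bins): the maximum power, the frequency at which it occurs, and
#' the fraction of total power carried by that maximum.
#'
#' @param frame Numeric sample vector (non-empty).
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector `c(power_max, freq_at_max,
#'   max_energy_fraction)`.
#' @export
power_spectrum_features <- function(frame, rate) {
  if (!length(frame)) {
    rlang::abort("Frame must be non-empty.", class = "cpsound_argument_error")
  }
  pg <- one_sided_periodogram(as.numeric(frame), rate)
  i <- which.max(pg$power)
  tot <- sum(pg$power)
  frac <- if (tot > 0) pg$power[i] / tot else 1
  stats::setNames(c(pg$power[i], pg$freqs[i], frac), spectrum_feature_names)
}

#' The full 27-dimensional frame feature vector
#'
#' Concatenates the 11 statistical features, 13 cepstral values and 3
#' power-spectrum summaries of a residual frame, in a fixed named order.
#'
#' @param res A `residual_frame` from [pca_residual()], or a plain numeric
#'   vector (then `rate` must be given).
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of length 27.
#' @export
feature_vector <- function(res, rate = NULL) {
  if (inherits(res, "residual_frame")) {
    x <- res$residual
    if (is.null(rate)) rate <- res$rate
  } else {
    x <- as.numeric(res)
  }
  if (is.null(rate)) {
    rlang::abort("`rate` must be supplied.", class = "cpsound_argument_error")
  }
  c(statistical_features(x, rate), mfcc_features(x, rate),
    power_spectrum_features(x, rate))
}
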