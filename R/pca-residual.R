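# PCA-residual denoising. The dominant periodic structure of a frame
# (heartbeat or breath template, typically > 80% of the signal) is captured
# by the leading principal components of a sub-window embedding and
# subtracted, leaving a residual that carries murmurs, wheezes, crackles and
# other aperiodic content for feature extraction.

#' Number of components reaching a cumulative contribution threshold
#'
#' @param explained_fractions Non-negative, non-increasing variance
#'   fractions summing to 1 (within tolerance).
#' @param threshold Cumulative contribution threshold in (0, 1]; the study
#'   value is 0.95 (the supported design range is 0.85--0.95).
#' @return The smallest `k` such that the first `k` fractions sum to at
#'   least `threshold`.
#' @export
#'
#' @examples
#' choose_num_components(c(0.90, 0.06, 0.04), 0.95) # 2
choose_num_components <- function(explained_fractions, threshold = 0.95) {
  if (!length(explained_fractions)) {
    rlang::abort("`explained_fractions` must be non-empty.",
                 class = "cpsound_argument_error")
  }
  if (any(explained_fractions < -1e-12)) {
    rlang::abort("Fractions must be non-negative.",
                 class = "cpsound_argument_error")
  }
  if (threshold <= 0 || threshold > 1) {
    rlang::abort("`threshold` must lie in (0, 1].",
                 class = "cpsound_argument_error")
  }
  cum <- cumsum(explained_fractions)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(explained_fractions)
  as.integer(k)
}

#' PCA residual of a single frame
#'
#' The frame is reshaped into `n_subwindows` consecutive equal sub-windows
#' (rows of an embedding matrix; any trailing remainder shorter than one
#' sub-window is carried into the residual unmodified). Columns are
#' mean-centered, the singular value decomposition provides variance
#' fractions, and the smallest number of leading components whose cumulative
#' contribution reaches `threshold` is reconstructed and subtracted from the
#' frame.
#'
#' @param frame Numeric sample vector (length >= `n_subwindows`).
#' @param rate Sampling rate in Hz (carried through for bookkeeping).
#' @param threshold Cumulative variance contribution to remove, in (0, 1].
#'   Default 0.95.
#' @param n_subwindows Number of embedding rows. Default 20, so a 2 s heart
#'   frame gives 100 ms sub-windows -- shorter than one cardiac cycle, so
#'   the cycle template repeats across rows and is low-rank.
#' @return An object of class `residual_frame`: list with `residual` (same
#'   length as `frame`), `removed_fraction`, `n_components_removed`,
#'   `contribution_threshold`, `rate`.
#' @export
pca_residual <- function(frame, rate, threshold = 0.95, n_subwindows = 20) {
  if (inherits(frame, "audio_recording")) {
    rate <- frame$rate
    frame <- frame$samples
  }
  if (length(frame) < n_subwindows) {
    rlang::abort("Frame must have at least `n_subwindows` samples.",
                 class = "cpsound_precondition_error")
  }
  if (threshold <= 0 || threshold > 1) {
    rlang::abort("`threshold` must lie in (0, 1].",
                 class = "cpsound_argument_error")
  }
  n <- length(frame)
  w <- n %/% n_subwindows
  used <- n_subwindows * w
  m <- matrix(frame[seq_len(used)], nrow = n_subwindows, ncol = w, byrow = TRUE)

  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  total_var <- sum(mc^2)

  if (total_var < 1e-24) {
    # all sub-windows identical: the template explains everything
    residual <- c(rep(0, used), frame[seq_len(n - used) + used])
    return(structure(list(residual = residual, removed_fraction = 1,
                          n_components_removed = 0L,
                          contribution_threshold = threshold, rate = rate),
                     class = "residual_frame"))
  }

  sv <- svd(mc)
  fractions <- sv$d^2 / sum(sv$d^2)
  k <- choose_num_components(fractions, threshold)
  recon <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  recon <- sweep(recon, 2, mu, `+`)

  res_mat <- m - recon
  residual <- c(as.numeric(t(res_mat)),
                if (n > used) frame[(used + 1):n] else numeric(0))

  structure(list(residual = residual,
                 removed_fraction = sum(fractions[seq_len(k)]),
                 n_components_removed = k,
                 contribution_threshold = threshold, rate = rate),
            class = "residual_frame")
}

#' @export
print.residual_frame <- function(x, ...) {
  cat(sprintf(
    "<residual_frame> %d samples; removed %d component(s) = %.4f of variance (threshold %.2f)\n",
    length(x$residual), x$n_components_removed, x$removed_fraction,
    x$contribution_threshold))
  invisible(x)
}
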