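#' Cut a recording into overlapping fixed-length frames
#'
#' Frames of `frame_length_s` seconds are taken every
#' `hop = frame_length_s * (1 - overlap)` seconds, so a signal of length `L`
#' seconds yields `floor((L - F) / H) + 1` frames; trailing samples that do
#' not fill a whole frame are dropped. A recording that yields fewer than
#' two frames is excluded from analysis (flagged, with zero usable frames)
#' rather than padded: a sample that cannot be divided into more than one
#' frame is ignored and not counted.
#'
#' Frame start times are quantized to whole samples (round-half-even of
#' `start_s * rate`).
#'
#' @param rec An [audio_recording()].
#' @param frame_length_s Frame length in seconds (> 0). The study grid is
#'   1, 1.5, 2 s for heart sounds and 3, 4, 5 s for lung sounds.
#' @param overlap Overlap fraction in \[0, 1); the study grid is 0, 0.2, 0.5.
#' @return An object of class `frame_set`: list with `frames` (a tibble with
#'   `frame_idx`, `start_s`, and a `samples` list-column), `frame_length_s`,
#'   `overlap`, `hop_s`, `rate`, `parent_id`, `label`, `excluded`.
#' @export
segment <- function(rec, frame_length_s, overlap = 0) {
  check_recording(rec)
  if (!is.numeric(frame_length_s) || frame_length_s <= 0) {
    rlang::abort("`frame_length_s` must be positive.",
                 class = "cpsound_argument_error")
  }
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    rlang::abort("`overlap` must lie in [0, 1).",
                 class = "cpsound_argument_error")
  }
  n <- length(rec$samples)
  flen <- round(frame_length_s * rec$rate)
  hop_s <- frame_length_s * (1 - overlap)

  starts <- integer(0)
  k <- 0
  repeat {
    s <- round(k * hop_s * rec$rate) # round-half-even sample quantization
    if (s + flen > n) break
    starts <- c(starts, s)
    k <- k + 1
  }

  excluded <- length(starts) < 2
  frames <- if (excluded) {
    tibble::tibble(frame_idx = integer(), start_s = numeric(),
                   samples = list())
  } else {
    tibble::tibble(
      frame_idx = seq_along(starts),
      start_s = starts / rec$rate,
      samples = purrr::map(starts, function(s) rec$samples[(s + 1):(s + flen)])
    )
  }

  structure(list(frames = frames, frame_length_s = frame_length_s,
                 overlap = overlap, hop_s = hop_s, rate = rec$rate,
                 parent_id = rec$id, label = rec$label,
                 sound_kind = rec$sound_kind, excluded = excluded),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> parent=%s: %d frame(s) of %g s, overlap %g%%%s\n",
              x$parent_id, nrow(x$frames), x$frame_length_s, 100 * x$overlap,
              if (x$excluded) " [excluded: < 2 frames]" else ""))
  invisible(x)
}

#' Expected frame count for a segmentation
#'
#' Closed-form count `floor((L - F) / H) + 1` for a signal of `L` seconds
#' (0 when `L < F`).
#'
#' @param signal_s,frame_length_s Signal and frame lengths in seconds.
#' @param overlap Overlap fraction in \[0, 1).
#' @return Integer frame count.
#' @export
n_frames_expected <- function(signal_s, frame_length_s, overlap = 0) {
  if (signal_s < frame_length_s) return(0L)
  hop <- frame_length_s * (1 - overlap)
  as.integer(floor((signal_s - frame_length_s) / hop + 1e-9) + 1)
}
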