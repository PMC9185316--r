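# Sample-level decisions by threshold voting over frame predictions, and
# the confusion-count metrics: accuracy = (TP+TN)/(TP+FN+FP+TN),
# specificity = TN/(FP+TN), sensitivity = TP/(TP+FN),
# precision = TP/(TP+FP), F1 = 2*sensitivity*precision/(sensitivity+precision).

#' The standard voting threshold grid (5% to 95% in 5% steps)
#' @return Numeric vector of 19 thresholds.
#' @export
vote_threshold_grid <- function() seq(0.05, 0.95, by = 0.05)

is_abnormal_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) x == "abnormal" else x > 0
}

#' Vote a sample-level decision from its frame labels
#'
#' The sample is called abnormal when the fraction of abnormal frames
#' strictly exceeds the threshold (a fraction exactly equal to the
#' threshold votes normal).
#'
#' @param frame_labels Frame predictions: `"normal"`/`"abnormal"`, logical,
#'   or 0/1.
#' @param threshold Voting threshold in (0, 1).
#' @param parent_id Optional sample identifier.
#' @return A one-row tibble: `parent_id`, `n_frames`, `n_abnormal_frames`,
#'   `abnormal_fraction`, `threshold`, `decision`.
#' @export
vote_sample <- function(frame_labels, threshold, parent_id = NA_character_) {
  if (!length(frame_labels)) {
    rlang::abort("Need at least one frame label.",
                 class = "cpsound_argument_error")
  }
  if (threshold <= 0 || threshold >= 1) {
    rlang::abort("`threshold` must lie in (0, 1).",
                 class = "cpsound_argument_error")
  }
  ab <- is_abnormal_label(frame_labels)
  frac <- mean(ab)
  tibble::tibble(
    parent_id = parent_id,
    n_frames = length(ab),
    n_abnormal_frames = sum(ab),
    abnormal_fraction = frac,
    threshold = threshold,
    decision = if (frac > threshold) "abnormal" else "normal"
  )
}

#' Metrics from confusion counts
#'
#' TP counts diseased samples classified abnormal; TN healthy classified
#' normal. Degenerate denominators (e.g. no positive calls) yield 0.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @param warn Warn when a denominator is zero (default `FALSE`).
#' @return A one-row tibble with the counts and `accuracy`, `specificity`,
#'   `sensitivity`, `precision`, `f1`.
#' @export
compute_metrics <- function(tp, fn, tn, fp, warn = FALSE) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      if (warn) rlang::warn(sprintf("Zero denominator for %s; reporting 0.", what))
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / (tp + fn + fp + tn)
  sp <- safe_div(tn, fp + tn, "specificity")
  se <- safe_div(tp, tp + fn, "sensitivity")
  pr <- safe_div(tp, tp + fp, "precision")
  f1 <- if (se + pr == 0) 0 else 2 * se * pr / (se + pr)
  tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                 accuracy = acc, specificity = sp, sensitivity = se,
                 precision = pr, f1 = f1)
}

#' Sweep the voting threshold grid
#'
#' For each threshold, votes every sample from its frame predictions,
#' accumulates confusion counts against the true sample labels, and
#' computes the five metrics.
#'
#' @param per_sample_frame_labels List of frame-prediction vectors, one per
#'   sample.
#' @param true_labels True sample labels, aligned with the list.
#' @param thresholds Threshold grid (default [vote_threshold_grid()]).
#' @return A tibble with one row per threshold: counts and metrics.
#' @export
sweep_thresholds <- function(per_sample_frame_labels, true_labels,
                             thresholds = vote_threshold_grid()) {
  if (length(per_sample_frame_labels) != length(true_labels)) {
    rlang::abort("Samples and labels are misaligned.",
                 class = "cpsound_argument_error")
  }
  truth <- is_abnormal_label(true_labels)
  fracs <- vapply(per_sample_frame_labels,
                  function(fl) mean(is_abnormal_label(fl)), numeric(1))
  purrr::map_dfr(thresholds, function(th) {
    call_ab <- fracs > th
    dplyr::bind_cols(
      tibble::tibble(threshold = th),
      compute_metrics(tp = sum(call_ab & truth), fn = sum(!call_ab & truth),
                      tn = sum(!call_ab & !truth), fp = sum(call_ab & !truth))
    )
  })
}
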