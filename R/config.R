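#' Pipeline configuration
#'
#' Validated parameter bundle for [run_pipeline()] / [kfold_evaluate()].
#' Segmentation parameters are restricted by default to the study grids --
#' frame lengths \{1, 1.5, 2\} s for heart and \{3, 4, 5\} s for lung,
#' overlaps \{0, 0.2, 0.5\} -- and the PCA threshold to \[0.85, 0.95\];
#' `allow_off_grid = TRUE` lifts the grid restriction.
#'
#' @param sound_kind `"heart"` or `"lung"`.
#' @param frame_length_s Frame length in seconds.
#' @param overlap Overlap fraction.
#' @param pca_threshold Cumulative PCA contribution to remove (default 0.95).
#' @param pca_subwindows Embedding rows for the PCA residual (default 20).
#' @param classifier List: `method` (one of the five ensembles or
#'   `"auto"` for randomized-trial selection), `n_learners`, `depth`,
#'   `learn_rate`, and for `"auto"` also `trials` and `n_evals`.
#' @param thresholds Voting threshold grid (default 5%--95%).
#' @param folds Fold count; defaults to 5 for heart, 3 for lung.
#' @param simulate Optional list `list(n_normal =, n_abnormal =)` used when
#'   [run_pipeline()] is called without a corpus.
#' @param allow_off_grid Allow off-grid segmentation values.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sound_kind = c("heart", "lung"),
                            frame_length_s = NULL, overlap = 0.2,
                            pca_threshold = 0.95, pca_subwindows = 20,
                            classifier = list(), thresholds = vote_threshold_grid(),
                            folds = NULL, simulate = NULL,
                            allow_off_grid = FALSE) {
  sound_kind <- match.arg(sound_kind)
  grid_len <- if (sound_kind == "heart") c(1, 1.5, 2) else c(3, 4, 5)
  if (is.null(frame_length_s)) {
    frame_length_s <- if (sound_kind == "heart") 2 else 5
  }
  if (!allow_off_grid) {
    if (!any(abs(frame_length_s - grid_len) < 1e-9)) {
      rlang::abort(sprintf(
        "`frame_length_s` = %g is off the %s grid {%s}; set allow_off_grid = TRUE to override.",
        frame_length_s, sound_kind, paste(grid_len, collapse = ", ")),
        class = "cpsound_config_error")
    }
    if (!any(abs(overlap - c(0, 0.2, 0.5)) < 1e-9)) {
      rlang::abort(sprintf(
        "`overlap` = %g is off the grid {0, 0.2, 0.5}; set allow_off_grid = TRUE to override.",
        overlap), class = "cpsound_config_error")
    }
  }
  if (pca_threshold < 0.85 - 1e-9 || pca_threshold > 0.95 + 1e-9) {
    rlang::abort("`pca_threshold` must lie in [0.85, 0.95].",
                 class = "cpsound_config_error")
  }
  known <- c("method", "n_learners", "depth", "learn_rate", "trials", "n_evals")
  if (length(setdiff(names(classifier), known))) {
    rlang::abort(sprintf("Unknown classifier key(s): %s",
                         paste(setdiff(names(classifier), known), collapse = ", ")),
                 class = "cpsound_config_error")
  }
  cls <- utils::modifyList(
    list(method = "adaboost", n_learners = 100, depth = 1, learn_rate = 1,
         trials = 5, n_evals = 20),
    classifier)
  if (!cls$method %in% c(ensemble_methods, "auto")) {
    rlang::abort(sprintf("Unknown classifier method: %s", cls$method),
                 class = "cpsound_config_error")
  }
  if (is.null(folds)) folds <- if (sound_kind == "heart") 5 else 3
  structure(list(sound_kind = sound_kind, frame_length_s = frame_length_s,
                 overlap = overlap, pca_threshold = pca_threshold,
                 pca_subwindows = pca_subwindows, classifier = cls,
                 thresholds = thresholds, folds = as.integer(folds),
                 simulate = simulate, allow_off_grid = allow_off_grid),
            class = "pipeline_config")
}
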