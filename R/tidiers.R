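#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics report
#'
#' One row per threshold (fold-averaged) or per fold and threshold.
#'
#' @param x A `metrics_report`.
#' @param by_fold Return per-fold rows instead of the fold average.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.metrics_report <- function(x, by_fold = FALSE, ...) {
  if (by_fold) x$by_fold else x$summary
}

#' One-row summary of a metrics report
#'
#' The fold-averaged metrics at the best-accuracy threshold.
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A one-row tibble with `fold_count`, `n_excluded`, `threshold`
#'   and the five metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  best <- x$summary[which.max(x$summary$accuracy), ]
  dplyr::bind_cols(
    tibble::tibble(fold_count = x$fold_count,
                   n_excluded = length(x$excluded_ids)),
    best
  )
}

#' Tidy a fitted ensemble model
#'
#' One row per base learner with its weight.
#'
#' @param x A `cps_model`.
#' @param ... Unused.
#' @return A tibble with `learner`, `weight`.
#' @export
tidy.cps_model <- function(x, ...) {
  tibble::tibble(learner = seq_along(x$learners), weight = x$alphas)
}

#' One-row summary of a fitted ensemble model
#'
#' @param x A `cps_model`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `n_learners`, `depth`,
#'   `learn_rate` and (when selected by [select_model()]) `objective`.
#' @export
glance.cps_model <- function(x, ...) {
  tibble::tibble(method = x$method, n_learners = length(x$learners),
                 depth = x$depth, learn_rate = x$learn_rate,
                 objective = x$objective %||% NA_real_)
}

#' Tidy a spectrum summary
#'
#' @param x A `spectrum_summary`.
#' @param ... Unused.
#' @return A tibble with `freq_hz`, `magnitude`.
#' @export
tidy.spectrum_summary <- function(x, ...) {
  tibble::tibble(freq_hz = x$freqs, magnitude = x$magnitude)
}
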