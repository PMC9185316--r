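# Frame-level ensemble classifiers. Five methods share one train/predict
# contract: bagging (bootstrap-aggregated trees), discrete AdaBoost,
# GentleBoost and LogitBoost (additive logistic regression with regression
# base learners), and RUSBoost (AdaBoost where each round trains on a
# class-balanced random undersample). The positive class is "abnormal";
# a frame is called abnormal when the ensemble score exceeds 0.

ensemble_methods <- c("bagging", "adaboost", "gentleboost", "logitboost",
                      "rusboost")

labels_to_pm1 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) return(ifelse(labels, 1, -1))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (all(u %in% c(0, 1))) return(ifelse(labels > 0, 1, -1))
    if (all(u %in% c(-1, 1))) return(labels)
    rlang::abort("Numeric labels must be 0/1 or -1/+1.",
                 class = "cpsound_argument_error")
  }
  if (!all(labels %in% c("normal", "abnormal"))) {
    rlang::abort("Labels must be 'normal'/'abnormal'.",
                 class = "cpsound_argument_error")
  }
  ifelse(labels == "abnormal", 1, -1)
}

feature_matrix <- function(features, schema = NULL) {
  df <- as.data.frame(features)
  num <- vapply(df, is.numeric, logical(1))
  df <- df[num]
  if (!is.null(schema)) {
    if (!all(schema %in% names(df))) {
      rlang::abort("Feature columns do not match the training schema.",
                   class = "cpsound_argument_error")
    }
    df <- df[schema]
  }
  as.matrix(df)
}

#' Train one frame-level ensemble classifier
#'
#' @param features Data frame (or matrix) of numeric frame features; any
#'   non-numeric columns are dropped.
#' @param labels Frame labels: `"normal"`/`"abnormal"` (or -1/+1, 0/1,
#'   logical). `"abnormal"` is the positive class.
#' @param method One of `"bagging"`, `"adaboost"`, `"gentleboost"`,
#'   `"logitboost"`, `"rusboost"`.
#' @param seed Integer seed; all randomness (bootstraps, undersamples)
#'   derives from it.
#' @param n_learners Ensemble size (boosting rounds or bagged trees).
#' @param depth Base-learner tree depth; 1 gives exhaustive decision stumps.
#' @param learn_rate Shrinkage for the boosting variants, in (0, 1].
#' @return An object of class `cps_model`.
#' @export
train_candidate <- function(features, labels, method = ensemble_methods,
                            seed = 1, n_learners = 100, depth = 1,
                            learn_rate = 1) {
  method <- match.arg(method)
  y <- labels_to_pm1(labels)
  X <- feature_matrix(features)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  n <- nrow(X)
  if (length(y) != n) {
    rlang::abort("`features` and `labels` lengths differ.",
                 class = "cpsound_argument_error")
  }
  n_pos <- sum(y > 0); n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("Training data must contain both classes.",
                 class = "cpsound_training_error")
  }
  if (method != "rusboost" && (n_pos < 2 || n_neg < 2)) {
    rlang::abort("Need at least 2 samples per class.",
                 class = "cpsound_training_error")
  }

  fit <- with_seed(seed, switch(method,
    bagging     = fit_bagging(X, y, n_learners, depth),
    adaboost    = fit_adaboost(X, y, n_learners, depth, learn_rate),
    gentleboost = fit_gentleboost(X, y, n_learners, depth, learn_rate),
    logitboost  = fit_logitboost(X, y, n_learners, depth, learn_rate),
    rusboost    = fit_rusboost(X, y, n_learners, depth, learn_rate)
  ))

  structure(c(fit, list(method = method, schema = colnames(X),
                        n_learners_requested = n_learners, depth = depth,
                        learn_rate = learn_rate, seed = as.integer(seed))),
            class = "cps_model")
}

fit_bagging <- function(X, y, M, depth) {
  n <- nrow(X)
  learners <- vector("list", M)
  for (m in seq_len(M)) {
    idx <- sample.int(n, n, replace = TRUE)
    learners[[m]] <- weak_class_fit(X[idx, , drop = FALSE], y[idx],
                                    rep(1 / n, n), depth)
  }
  list(learners = learners, alphas = rep(1 / M, M), kind = "class")
}

adaboost_core <- function(X, y, M, depth, lr, sampler = NULL) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  rounds <- list()
  for (m in seq_len(M)) {
    if (is.null(sampler)) {
      h <- weak_class_fit(X, y, w, depth)
    } else {
      idx <- sampler(w)
      rounds[[length(rounds) + 1]] <- table(y[idx])
      h <- weak_class_fit(X[idx, , drop = FALSE], y[idx],
                          w[idx] / sum(w[idx]), depth)
    }
    pred <- weak_class_predict(h, X)
    err <- sum(w[pred != y])
    if (err >= 0.5 - 1e-12) break
    alpha <- if (err <= 1e-12) 10 else lr * 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1]] <- h
    alphas <- c(alphas, alpha)
    if (err <= 1e-12) break
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas, kind = "class",
       round_class_counts = rounds)
}

fit_adaboost <- function(X, y, M, depth, lr) {
  adaboost_core(X, y, M, depth, lr)
}

fit_rusboost <- function(X, y, M, depth, lr) {
  pos <- which(y > 0); neg <- which(y < 0)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  sampler <- function(w) {
    c(minority, sample(majority, length(minority)))
  }
  adaboost_core(X, y, M, depth, lr, sampler = sampler)
}

fit_gentleboost <- function(X, y, M, depth, lr) {
  n <- nrow(X)
  F <- numeric(n)
  learners <- vector("list", M)
  for (m in seq_len(M)) {
    w <- exp(-y * F)
    w <- w / sum(w)
    f <- weak_reg_fit(X, y, w, depth)
    learners[[m]] <- f
    F <- F + lr * weak_reg_predict(f, X)
  }
  list(learners = learners, alphas = rep(lr, M), kind = "reg")
}

fit_logitboost <- function(X, y, M, depth, lr) {
  n <- nrow(X)
  y01 <- (y + 1) / 2
  F <- numeric(n)
  p <- rep(0.5, n)
  learners <- vector("list", M)
  for (m in seq_len(M)) {
    w <- pmax(p * (1 - p), 1e-10)
    z <- pmin(pmax((y01 - p) / w, -4), 4)
    f <- weak_reg_fit(X, z, w / sum(w), depth)
    learners[[m]] <- f
    F <- F + 0.5 * lr * weak_reg_predict(f, X)
    p <- 1 / (1 + exp(-2 * F))
  }
  list(learners = learners, alphas = rep(0.5 * lr, M), kind = "reg")
}

#' Ensemble score for new frames
#'
#' The additive score of the fitted ensemble; frames with score > 0 are
#' classified abnormal.
#'
#' @param model A `cps_model`.
#' @param features Feature table with the training columns.
#' @return Numeric score vector.
#' @export
predict_score <- function(model, features) {
  X <- feature_matrix(features, schema = model$schema)
  if (!length(model$learners)) return(rep(0, nrow(X)))
  preds <- vapply(seq_along(model$learners), function(m) {
    h <- model$learners[[m]]
    if (model$kind == "class") model$alphas[m] * weak_class_predict(h, X)
    else model$alphas[m] * weak_reg_predict(h, X)
  }, numeric(nrow(X)))
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  unname(rowSums(preds))
}

#' Predict frame labels
#'
#' @param model A `cps_model`.
#' @param features Feature table with the training columns.
#' @return Factor of `"normal"`/`"abnormal"`, one per row.
#' @export
predict_frames <- function(model, features) {
  score <- predict_score(model, features)
  factor(ifelse(score > 0, "abnormal", "normal"),
         levels = c("normal", "abnormal"))
}

#' @export
print.cps_model <- function(x, ...) {
  cat(sprintf("<cps_model> method=%s, %d learner(s), depth %d, lr %g\n",
              x$method, length(x$learners), x$depth, x$learn_rate))
  if (!is.null(x$objective)) {
    cat(sprintf("  selection objective (CV accuracy): %.4f\n", x$objective))
  }
  invisible(x)
}
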