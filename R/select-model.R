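# Model selection: several independent trials, each drawing one of the five
# ensemble methods at random and tuning its hyperparameters (ensemble size,
# tree depth, learning rate) by Bayesian optimization of a cross-validated
# accuracy; the trial with the best observed objective wins.

stratified_fold_ids <- function(y, k) {
  # deal each class round-robin, continuing the fold counter across classes
  # so per-class counts stay within 1 of proportional AND total fold sizes
  # stay within 1 of n/k
  fold <- integer(length(y))
  at <- 0L
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((at + seq_along(idx) - 1L) %% k) + 1L
    at <- at + length(idx)
  }
  fold
}

cv_accuracy <- function(X, y, method, k, seed, n_learners, depth, learn_rate) {
  fold <- with_seed(seed, stratified_fold_ids(y, k))
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
    m <- train_candidate(X[tr, , drop = FALSE], y[tr], method, seed = seed + f,
                         n_learners = n_learners, depth = depth,
                         learn_rate = learn_rate)
    mean(sign(predict_score(m, X[!tr, , drop = FALSE])) ==
           ifelse(y[!tr] > 0, 1, -1))
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

# Gaussian-process expected improvement over the unit cube.
gp_ei_propose <- function(Xobs, yobs, n_cand = 200) {
  d <- ncol(Xobs)
  cand <- matrix(stats::runif(n_cand * d), ncol = d)
  ell <- 0.3
  sf2 <- max(stats::var(yobs), 1e-6)
  kfun <- function(A, B) {
    D <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sf2 * exp(-0.5 * pmax(D, 0) / ell^2)
  }
  K <- kfun(Xobs, Xobs) + diag(1e-6 * sf2, nrow(Xobs))
  mu0 <- mean(yobs)
  alpha <- solve(K, yobs - mu0)
  Ks <- kfun(cand, Xobs)
  mu <- mu0 + as.numeric(Ks %*% alpha)
  v <- pmax(sf2 - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
  s <- sqrt(v)
  best <- max(yobs)
  z <- (mu - best) / s
  ei <- (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
  cand[which.max(ei), ]
}

decode_params <- function(u, n_learners_range, depth_range, lr_range) {
  list(
    n_learners = as.integer(round(n_learners_range[1] +
                                    u[1] * diff(n_learners_range))),
    depth = as.integer(round(depth_range[1] + u[2] * diff(depth_range))),
    learn_rate = lr_range[1] + u[3] * diff(lr_range)
  )
}

#' Select a frame classifier by randomized trials with Bayesian optimization
#'
#' Runs `n_trials` independent trials. Each trial draws one ensemble method
#' at random, then spends `n_evals` objective evaluations tuning
#' (`n_learners`, `depth`, `learn_rate`) by expected-improvement Bayesian
#' optimization (Latin-hypercube initial design, Gaussian-process
#' surrogate). The objective is mean stratified `cv_folds`-fold accuracy on
#' the training data. The best observation across all trials determines the
#' returned model, which is refit on the full training data.
#'
#' @inheritParams train_candidate
#' @param n_trials Number of random-method trials (default 5).
#' @param n_evals Objective evaluations per trial (default 20).
#' @param cv_folds Internal cross-validation folds (default 3).
#' @param methods Candidate methods (default all five).
#' @param n_learners_range,depth_range,lr_range Search bounds; defaults
#'   \[50, 500\], \[1, 4\], \[0.01, 1\].
#' @return A `cps_model` with extra fields `objective` (best CV accuracy)
#'   and `trials` (a tibble of per-trial methods, tuned parameters and
#'   objectives).
#' @export
select_model <- function(features, labels, n_trials = 5, seed = 1,
                         n_evals = 20, cv_folds = 3,
                         methods = ensemble_methods,
                         n_learners_range = c(50, 500),
                         depth_range = c(1, 4), lr_range = c(0.01, 1)) {
  y <- labels_to_pm1(labels)
  X <- feature_matrix(features)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))

  trial_plan <- with_seed(seed, tibble::tibble(
    trial = seq_len(n_trials),
    method = sample(methods, n_trials, replace = TRUE),
    trial_seed = sample.int(2^30, n_trials)
  ))

  trials <- purrr::pmap(trial_plan, function(trial, method, trial_seed) {
    n_init <- min(max(3, n_evals %/% 3), n_evals)
    U <- with_seed(trial_seed, lhs::randomLHS(n_init, 3))
    obs_u <- NULL
    obs_y <- numeric(0)
    for (i in seq_len(n_evals)) {
      u <- if (i <= n_init) U[i, ] else {
        with_seed(trial_seed + i, gp_ei_propose(obs_u, obs_y))
      }
      pr <- decode_params(u, n_learners_range, depth_range, lr_range)
      obj <- cv_accuracy(X, y, method, cv_folds, trial_seed + 1000 + i,
                         pr$n_learners, pr$depth, pr$learn_rate)
      obs_u <- rbind(obs_u, u)
      obs_y <- c(obs_y, obj)
    }
    best_i <- which.max(obs_y)
    pr <- decode_params(obs_u[best_i, ], n_learners_range, depth_range,
                        lr_range)
    tibble::tibble(trial = trial, method = method, trial_seed = trial_seed,
                   n_learners = pr$n_learners, depth = pr$depth,
                   learn_rate = pr$learn_rate, objective = obs_y[best_i])
  })
  trials <- dplyr::bind_rows(trials)

  best <- trials[which.max(trials$objective), ]
  model <- train_candidate(X, y, best$method, seed = best$trial_seed,
                           n_learners = best$n_learners, depth = best$depth,
                           learn_rate = best$learn_rate)
  model$objective <- best$objective
  model$trials <- trials
  model
}
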