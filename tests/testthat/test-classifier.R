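test_that("all five methods reach zero training error on separable data", {
  X <- make_separable_2d()
  y <- separable_labels()
  for (m in c("bagging", "adaboost", "gentleboost", "logitboost", "rusboost")) {
    mod <- train_candidate(X, y, m, seed = 21, n_learners = 30)
    err <- mean(as.character(predict_frames(mod, X)) != y)
    expect_equal(err, 0, info = m)
  }
})

test_that("training is deterministic given data, method and seed", {
  X <- make_separable_2d(seed = 22)
  y <- separable_labels()
  set.seed(99)
  grid <- data.frame(x1 = runif(50, -3, 3), x2 = runif(50, -3, 3))
  for (m in c("bagging", "adaboost", "rusboost")) {
    p1 <- predict_frames(train_candidate(X, y, m, seed = 5, n_learners = 20), grid)
    p2 <- predict_frames(train_candidate(X, y, m, seed = 5, n_learners = 20), grid)
    expect_identical(p1, p2, info = m)
  }
})

test_that("AdaBoost's first stump matches the exhaustive optimal stump", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- round(rnorm(n), 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    w <- rep(1 / n, n)
    fit <- cpsound:::stump_class_fit(matrix(x, ncol = 1), y, w)
    pred <- cpsound:::stump_class_predict(fit, matrix(x, ncol = 1))
    expect_equal(sum(w[pred != y]), oracle_stump_error(x, y, w),
                 tolerance = 1e-12)
  }
})

test_that("a single-stump AdaBoost model is that stump's decision", {
  X <- make_separable_2d(seed = 24)
  y <- separable_labels()
  mod <- train_candidate(X, y, "adaboost", seed = 3, n_learners = 1)
  expect_length(mod$learners, 1)
  stump_pred <- cpsound:::weak_class_predict(mod$learners[[1]], as.matrix(X))
  ens_pred <- ifelse(as.character(predict_frames(mod, X)) == "abnormal", 1, -1)
  expect_identical(ens_pred, stump_pred)
})

test_that("boosting training error is non-increasing on separable data", {
  X <- make_separable_2d(30, margin = 0.5, seed = 25)
  y <- rep(c(-1, 1), each = 30)
  for (m in c("adaboost", "gentleboost", "logitboost")) {
    errs <- vapply(c(1, 5, 15, 40), function(M) {
      mod <- train_candidate(X, y, m, seed = 6, n_learners = M)
      mean(sign(predict_score(mod, X)) != y)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-12), info = m)
  }
})

test_that("RUSBoost rounds train on class-balanced subsamples", {
  set.seed(26)
  X <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  y <- rep(c("normal", "abnormal"), c(95, 5))
  mod <- train_candidate(X, y, "rusboost", seed = 7, n_learners = 10)
  counts <- mod$round_class_counts
  expect_gt(length(counts), 0)
  for (tab in counts) {
    expect_equal(unname(tab["-1"]), unname(tab["1"]))
    expect_equal(unname(tab["1"]), 5L)
  }
})

test_that("predictions are row-independent and schema-checked", {
  X <- make_separable_2d(seed = 27)
  y <- separable_labels()
  mod <- train_candidate(X, y, "adaboost", seed = 8, n_learners = 10)
  perm <- sample(nrow(X))
  expect_identical(predict_frames(mod, X[perm, ]),
                   predict_frames(mod, X)[perm])
  expect_error(predict_frames(mod, data.frame(bad = 1:3)),
               class = "cpsound_argument_error")
  expect_error(train_candidate(X, rep("normal", nrow(X)), "adaboost"),
               class = "cpsound_training_error")
})

test_that("all five methods share the train/predict contract", {
  X <- make_separable_2d(seed = 28)
  y <- separable_labels()
  for (m in c("bagging", "adaboost", "gentleboost", "logitboost", "rusboost")) {
    mod <- train_candidate(X, y, m, seed = 9, n_learners = 10, depth = 2)
    p <- predict_frames(mod, X)
    expect_s3_class(mod, "cps_model")
    expect_length(p, nrow(X))
    expect_true(all(levels(p) == c("normal", "abnormal")))
    g <- glance(mod)
    expect_equal(g$method, m)
  }
})

test_that("randomized-trial selection returns the best-objective trial", {
  X <- make_separable_2d(seed = 29)
  y <- separable_labels()
  mod <- select_model(X, y, n_trials = 3, seed = 30, n_evals = 4,
                      n_learners_range = c(5, 20))
  expect_equal(nrow(mod$trials), 3)
  expect_equal(mod$objective, max(mod$trials$objective))
  expect_gte(mod$objective, 0.95)

  mod1 <- select_model(X, y, n_trials = 1, seed = 31, n_evals = 3,
                       n_learners_range = c(5, 20))
  expect_equal(nrow(mod1$trials), 1)
  expect_s3_class(mod1, "cps_model")
})
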