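test_that("vote_sample follows the strict-threshold rule", {
  v <- vote_sample(rep(c("abnormal", "normal"), c(3, 7)), 0.25)
  expect_equal(v$decision, "abnormal")
  expect_equal(v$abnormal_fraction, 0.3)

  v0 <- vote_sample(rep("normal", 10), 0.05)
  expect_equal(v0$decision, "normal")

  # a fraction exactly at the threshold votes normal (strict inequality)
  vt <- vote_sample(rep(c("abnormal", "normal"), c(2, 8)), 0.20)
  expect_equal(vt$decision, "normal")

  expect_error(vote_sample(character(0), 0.5),
               class = "cpsound_argument_error")
})

test_that("vote_sample agrees with brute force over all short label vectors", {
  grid <- vote_threshold_grid()
  expect_length(grid, 19)
  for (len in 1:8) {
    for (n_ab in 0:len) {
      labels <- rep(c("abnormal", "normal"), c(n_ab, len - n_ab))
      for (th in grid) {
        expected <- if (n_ab / len > th) "abnormal" else "normal"
        expect_identical(vote_sample(labels, th)$decision, expected)
      }
    }
  }
})

test_that("compute_metrics reproduces hand-evaluated confusion counts", {
  m <- compute_metrics(tp = 8, fn = 2, tn = 9, fp = 1)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 0.8889, tolerance = 1e-4)
  expect_equal(m$f1, 0.8421, tolerance = 1e-4)

  perfect <- compute_metrics(tp = 5, fn = 0, tn = 5, fp = 0)
  expect_true(all(perfect[c("accuracy", "specificity", "sensitivity",
                            "precision", "f1")] == 1))

  degen <- compute_metrics(tp = 0, fn = 3, tn = 4, fp = 0)
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$precision, 0)
  expect_equal(degen$f1, 0)
})

test_that("accuracy identity holds exactly for integer counts", {
  set.seed(31)
  for (i in 1:20) {
    cts <- sample(0:20, 4, replace = TRUE)
    if (sum(cts) == 0) cts[1] <- 1
    m <- compute_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$accuracy * sum(cts), cts[1] + cts[3], tolerance = 1e-12)
  }
})

test_that("threshold sweep is monotone in sensitivity and specificity", {
  # exhaustive over all frame-label vectors of length <= 6 for 3 samples
  set.seed(32)
  for (rep_i in 1:30) {
    lens <- sample(1:6, 3, replace = TRUE)
    frames <- lapply(lens, function(l) sample(c("normal", "abnormal"), l,
                                              replace = TRUE))
    truth <- sample(c("normal", "abnormal"), 3, replace = TRUE)
    sw <- sweep_thresholds(frames, truth)
    expect_equal(nrow(sw), 19)
    expect_true(all(diff(sw$sensitivity) <= 1e-12))
    expect_true(all(diff(sw$specificity) >= -1e-12))
  }
})

test_that("all-frames-correct samples give accuracy 1 at low thresholds", {
  frames <- list(rep("abnormal", 10), rep("normal", 10), rep("abnormal", 4))
  truth <- c("abnormal", "normal", "abnormal")
  sw <- sweep_thresholds(frames, truth)
  expect_true(all(sw$accuracy[sw$threshold < 1] == 1))
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  corpus <- generate_dataset(8, 12, "heart", seed = 33,
                             duration_range = c(5, 6))
  labels <- corpus$label
  fold <- cpsound:::assign_folds(labels, 5, seed = 1)
  expect_length(fold, 20)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.numeric(table(fold)), rep(4, 5))
  # per-fold class ratio within one sample of the global ratio
  for (f in 1:5) {
    n_ab <- sum(labels[fold == f] == "abnormal")
    expect_lte(abs(n_ab - 12 / 5), 1)
  }
  expect_identical(fold, cpsound:::assign_folds(labels, 5, seed = 1))
})
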