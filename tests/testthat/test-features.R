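test_that("statistical features reproduce hand-computed values", {
  f <- statistical_features(c(1, 2, 3, 4, 5))
  expect_equal(unname(f["mean"]), 3)
  expect_equal(unname(f["std"]), sqrt(2.5), tolerance = 1e-4)
  expect_equal(unname(f["mean_abs_dev"]), 1.2)
  expect_equal(unname(f["median"]), 3)
  expect_equal(unname(f["q1"]), 2)
  expect_equal(unname(f["q3"]), 4)
  expect_equal(unname(f["iqr"]), 2)
  expect_equal(unname(f["skewness"]), 0)
})

test_that("constant frames obey the degenerate conventions", {
  f <- statistical_features(rep(2, 100))
  expect_equal(unname(f[c("std", "iqr", "shannon_entropy", "skewness",
                          "kurtosis", "spectral_entropy")]),
               rep(0, 6))
})

test_that("uniform bin occupancy gives 4 bits of Shannon entropy", {
  # 16 bins, each hit exactly 8 times
  x <- rep((0:15) / 16 + 1 / 32, 8)
  f <- statistical_features(x)
  expect_equal(unname(f["shannon_entropy"]), 4, tolerance = 1e-9)
})

test_that("quartile ordering holds under permutation", {
  set.seed(12)
  for (i in 1:20) {
    x <- sample(rnorm(50))
    f <- statistical_features(x)
    expect_lte(f[["q1"]], f[["median"]])
    expect_lte(f[["median"]], f[["q3"]])
    expect_gte(f[["iqr"]], 0)
  }
})

test_that("MFCC block has 13 values with the scaling law of log/DCT algebra", {
  set.seed(13)
  frame <- rnorm(4000)
  m1 <- mfcc_features(frame, 2000)
  expect_length(m1, 13)
  m2 <- mfcc_features(2 * frame, 2000)
  expect_equal(unname(m2[1:12]), unname(m1[1:12]), tolerance = 1e-6)
  expect_equal(unname(m2[13] - m1[13]), log(4), tolerance = 1e-9)
})

test_that("MFCC of a zero frame is finite with floored log energy", {
  m <- mfcc_features(numeric(2000), 2000)
  expect_true(all(is.finite(m)))
  expect_equal(unname(m[13]), log(1e-12))
  expect_error(mfcc_features(rnorm(10), 2000),
               class = "cpsound_precondition_error")
})

test_that("power spectrum features locate peaks and fractions", {
  tone <- sin(2 * pi * 250 * (0:3999) / 2000)
  p <- power_spectrum_features(tone, 2000)
  expect_equal(unname(p["freq_at_max"]), 250)

  const <- rep(1, 1000)
  pc <- power_spectrum_features(const, 2000)
  expect_equal(unname(pc["freq_at_max"]), 0)
  expect_equal(unname(pc["max_energy_fraction"]), 1, tolerance = 1e-9)

  two <- sin(2 * pi * 200 * (0:3999) / 2000) + sin(2 * pi * 400 * (0:3999) / 2000)
  pt <- power_spectrum_features(two, 2000)
  expect_equal(unname(pt["max_energy_fraction"]), 0.5, tolerance = 0.02)
})

test_that("the full vector is 27 long with an 16/11 frequency/statistics split", {
  res <- pca_residual(rnorm(4000), 2000)
  v <- feature_vector(res)
  expect_length(v, 27)
  expect_named(v, feature_names())
  # 13 cepstral + 3 spectral = 16 frequency-domain features
  expect_length(grep("^mfcc_|^log_energy", names(v)), 13)
  expect_length(v[c(sprintf("mfcc_%02d", 1:12), "log_energy",
                    "power_max", "freq_at_max", "max_energy_fraction")], 16)
  # determinism
  expect_identical(v, feature_vector(res))
})

test_that("spectral entropy approaches its analytic extremes", {
  tone <- sin(2 * pi * 100 * (0:3999) / 2000)
  expect_lte(statistical_features(tone)[["spectral_entropy"]], 0.05)
  set.seed(14)
  noise <- rnorm(4000)
  expect_gte(statistical_features(noise)[["spectral_entropy"]], 0.9)
})

test_that("all 27 features are finite on a fuzz of generator frames", {
  set.seed(15)
  n_bad <- 0
  for (i in 1:250) {
    kind <- if (i %% 2) "heart" else "lung"
    x <- if (kind == "heart") {
      generate_heart(heart_spec(bpm = runif(1, 50, 80), duration_s = 0.6,
                                murmur_amp = runif(1, 0, 0.8),
                                seed = i))$samples[1:600]
    } else {
      generate_lung(lung_spec(breaths_per_min = runif(1, 12, 20),
                              duration_s = 0.6,
                              wheeze_amp = runif(1, 0, 0.6),
                              crackle_rate = runif(1, 0, 2),
                              seed = i))$samples[1:600]
    }
    rate <- if (kind == "heart") 2000 else 8000
    v <- feature_vector(pca_residual(x, rate, n_subwindows = 10))
    if (!all(is.finite(v))) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})
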