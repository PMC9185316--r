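test_that("heart generator places the stated number of S1/S2 events", {
  rec <- generate_heart(heart_spec(bpm = 60, duration_s = 10, seed = 4))
  ev <- attr(rec, "events")
  expect_equal(sum(ev$type == "S1"), 10)
  expect_equal(sum(ev$type == "S2"), 10)
  expect_equal(rec$label, "normal")
  expect_lte(max(abs(rec$samples)), 1)
})

test_that("heart generator is deterministic given the spec", {
  spec <- heart_spec(bpm = 72, duration_s = 8, murmur_amp = 0.4, seed = 9)
  expect_identical(generate_heart(spec)$samples, generate_heart(spec)$samples)
})

test_that("a murmur raises 150-400 Hz band energy by at least 3 dB", {
  normal <- generate_heart(heart_spec(bpm = 60, duration_s = 10, seed = 5))
  abnormal <- generate_heart(heart_spec(bpm = 60, duration_s = 10,
                                        murmur_amp = 0.5, seed = 5))
  gain_db <- 10 * log10(
    band_energy(abnormal$samples, 2000, 150, 400) /
      band_energy(normal$samples, 2000, 150, 400))
  expect_gte(gain_db, 3)
  expect_equal(abnormal$label, "abnormal")
})

test_that("lung generator produces the stated breath count and wheeze tone", {
  rec <- generate_lung(lung_spec(breaths_per_min = 15, duration_s = 20, seed = 6))
  expect_equal(nrow(attr(rec, "events")), 5)
  expect_equal(rec$label, "normal")
  expect_lte(max(abs(rec$samples)), 1)

  wz <- generate_lung(lung_spec(breaths_per_min = 15, duration_s = 20,
                                wheeze_amp = 0.4, wheeze_freq = 400, seed = 6))
  expect_equal(wz$label, "abnormal")
  # expiration window of breath 2: phase 0.5-1 of the second cycle
  period <- 60 / 15
  i0 <- round((period * 1.55) * wz$rate); i1 <- round((period * 1.95) * wz$rate)
  peak <- fft_peak_freq(wz$samples[i0:i1], wz$rate)
  expect_lte(abs(peak - 400), 5)
})

test_that("lung label reflects abnormality parameters exactly", {
  expect_equal(generate_lung(lung_spec(crackle_rate = 1, seed = 1))$label,
               "abnormal")
  expect_equal(generate_lung(lung_spec(seed = 1))$label, "normal")
})

test_that("noise mixing honours the SNR definition", {
  clean <- generate_heart(heart_spec(duration_s = 5, seed = 2))
  m <- mix_with_noise(clean, "ward", snr_db = 0, seed = 3)
  added <- m$primary$samples - clean$samples
  ratio <- mean(clean$samples^2) / mean(added^2)
  expect_equal(ratio, 1, tolerance = 0.01)
})

test_that("identity coupling cancels exactly; a frequency shift does not", {
  clean <- generate_heart(heart_spec(duration_s = 5, seed = 2))
  m <- mix_with_noise(clean, "ward", snr_db = 0, seed = 3)
  recovered <- m$primary$samples - m$reference$samples
  expect_lt(max(abs(recovered - clean$samples)), 1e-12)

  ms <- mix_with_noise(clean, "ward", snr_db = 0,
                       coupling = noise_coupling(freq_shift = 1.08), seed = 3)
  coupled <- ms$primary$samples - clean$samples
  residual <- ms$primary$samples - ms$reference$samples - clean$samples
  band_res <- band_energy(residual, clean$rate, 150, 450)
  band_coupled <- band_energy(coupled, clean$rate, 150, 450)
  expect_gt(band_res / band_coupled, 0.1)
})

test_that("generate_dataset yields exact counts, labels and reproducibility", {
  d <- generate_dataset(5, 5, "heart", seed = 1)
  expect_equal(nrow(d), 10)
  expect_equal(sum(d$label == "normal"), 5)
  expect_equal(sum(d$label == "abnormal"), 5)
  d2 <- generate_dataset(5, 5, "heart", seed = 1)
  expect_identical(d$recording[[3]]$samples, d2$recording[[3]]$samples)

  lab_only <- generate_dataset(0, 3, "lung", seed = 2,
                               duration_range = c(8, 10))
  expect_true(all(lab_only$label == "abnormal"))
  expect_true(all(vapply(lab_only$recording,
                         function(r) r$label == "abnormal", logical(1))))
})

test_that("generated signals stay within full scale across seeds", {
  for (s in 1:5) {
    h <- generate_heart(heart_spec(bpm = 50 + 6 * s, duration_s = 4,
                                   murmur_amp = (s %% 2) * 0.5, seed = s))
    expect_lte(max(abs(h$samples)), 1)
  }
})

test_that("corpus round-trips through WAV files and a manifest", {
  d <- generate_dataset(1, 1, "heart", seed = 7, duration_range = c(5, 6))
  dir <- withr::local_tempdir()
  write_corpus(d, dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  back <- read_wav(file.path(dir, paste0(d$id[1], ".wav")))
  expect_lte(max(abs(back$samples - d$recording[[1]]$samples)), 1 / 32768)
})
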