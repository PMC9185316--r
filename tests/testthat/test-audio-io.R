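test_that("16-bit WAV round trip stays within one quantization step", {
  set.seed(1)
  rec <- audio_recording(runif(4000, -1, 1), 2000)
  tf <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, tf)
  back <- read_wav(tf)
  expect_equal(back$rate, 2000)
  expect_length(back$samples, 4000)
  expect_lte(max(abs(back$samples - rec$samples)), 1 / 32768)
})

test_that("an all-zero 1 s file reads back as 2000 zero samples at 2000 Hz", {
  tf <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_recording(numeric(2000), 2000), tf)
  back <- read_wav(tf)
  expect_equal(back$rate, 2000)
  expect_identical(back$samples, numeric(2000))
})

test_that("stereo input is averaged to mono (x and -x cancel)", {
  # hand-build a 2-channel 16-bit file with channels x and -x
  x <- as.integer(round(sin(2 * pi * 50 * (0:999) / 2000) * 20000))
  interleaved <- as.integer(rbind(x, -x))
  tf <- withr::local_tempfile(fileext = ".wav")
  con <- file(tf, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(interleaved) * 2), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(2000L, 8000L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(interleaved) * 2), con, size = 4, endian = "little")
  writeBin(interleaved, con, size = 2, endian = "little")
  close(con)
  back <- read_wav(tf)
  expect_length(back$samples, 1000)
  expect_equal(max(abs(back$samples)), 0)
})

test_that("read errors are classified", {
  expect_error(read_wav(file.path(tempdir(), "no_such.wav")),
               class = "cpsound_not_found_error")
  tf <- withr::local_tempfile(fileext = ".wav")
  writeLines("not a wav", tf)
  expect_error(read_wav(tf), class = "cpsound_format_error")
})

test_that("resampling preserves tone location, duration and identity", {
  rec <- sine_rec(100, 8000, 1)
  down <- resample_audio(rec, 2000)
  expect_equal(length(down$samples), 2000, tolerance = 1e-9)
  expect_equal(fft_peak_freq(down$samples, 2000), 100, tolerance = 1.01)
  expect_identical(resample_audio(rec, 8000)$samples, rec$samples)
  expect_error(resample_audio(rec, -1), class = "cpsound_argument_error")
})

test_that("heart filter passes 100 Hz, rejects 1600 Hz, preserves zero", {
  in_band <- sine_rec(100, 8000, 2)
  out <- heart_filter(in_band)
  expect_lt(abs(20 * log10(rms(out$samples) / rms(in_band$samples))), 1)
  stop_band <- sine_rec(1600, 8000, 2)
  att <- 20 * log10(rms(heart_filter(stop_band)$samples) / rms(stop_band$samples))
  expect_lt(att, -20)
  z <- heart_filter(audio_recording(numeric(4000), 8000))
  expect_equal(max(abs(z$samples)), 0)
  expect_error(heart_filter(sine_rec(10, 500, 1)),
               class = "cpsound_precondition_error")
})

test_that("lung filter passes 500 Hz and rejects 20 Hz", {
  in_band <- sine_rec(500, 8000, 2, kind = "lung")
  expect_lt(abs(20 * log10(rms(lung_filter(in_band)$samples) /
                             rms(in_band$samples))), 1)
  low <- sine_rec(20, 8000, 2, kind = "lung")
  expect_lt(20 * log10(rms(lung_filter(low)$samples) / rms(low$samples)), -20)
  expect_error(lung_filter(sine_rec(500, 4000, 1)),
               class = "cpsound_precondition_error")
})

test_that("filters are linear and zero-phase", {
  set.seed(2)
  x <- audio_recording(rnorm(4000), 8000)
  y <- audio_recording(rnorm(4000), 8000)
  ab <- audio_recording(2 * x$samples + 3 * y$samples, 8000)
  lhs <- heart_filter(ab)$samples
  rhs <- 2 * heart_filter(x)$samples + 3 * heart_filter(y)$samples
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  tone <- sine_rec(200, 8000, 2)
  filt <- heart_filter(tone)$samples
  cc <- stats::ccf(filt, tone$samples, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})
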