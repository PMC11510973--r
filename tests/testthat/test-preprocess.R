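make_tone <- function(freq, fs = 128, secs = 10, amp = 1) {
  amp * sin(2 * pi * freq * (0:(secs * fs - 1)) / fs)
}

test_that("CSV recordings round-trip and are validated", {
  rec <- gen_eeg_segment("NM", tiny_synth_cfg(), seed = 61)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, f)
  back <- read_recording(f, "EEG")
  expect_equal(back$samples, rec$samples, tolerance = 1e-10)
  expect_equal(back$fs, rec$fs, tolerance = 1e-9)
  expect_identical(back$channel_names, eeg_montage())

  # shuffled channel columns come back in canonical montage order
  df <- utils::read.csv(f, check.names = FALSE)
  perm <- c(1, 1 + sample(ncol(df) - 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, perm], f2, row.names = FALSE)
  back2 <- read_recording(f2, "EEG")
  expect_identical(back2$channel_names, eeg_montage())
  expect_equal(back2$samples, rec$samples, tolerance = 1e-10)

  # non-uniform time grid is rejected with the offending line
  df$time[5] <- df$time[5] + 0.01
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f3, row.names = FALSE)
  expect_error(read_recording(f3, "EEG"), "non-uniform time grid")

  # unknown channel in a full-size montage is rejected
  names(df)[2] <- "BOGUS"
  df$time <- seq(0, by = 1 / 128, length.out = nrow(df))
  f4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f4, row.names = FALSE)
  expect_error(read_recording(f4, "EEG"), "unknown EEG channel")
})

test_that("EDF and CSV dialects of the same array agree to quantization", {
  rec <- gen_eeg_segment("NM", tiny_synth_cfg(), seed = 62)
  fc <- withr::local_tempfile(fileext = ".csv")
  fe <- withr::local_tempfile(fileext = ".edf")
  write_recording_csv(rec, fc)
  write_recording_edf(rec, fe)
  from_csv <- read_recording(fc, "EEG", dialect = "csv")
  from_edf <- read_recording(fe, "EEG", dialect = "edf")
  expect_identical(from_edf$channel_names, from_csv$channel_names)
  expect_equal(from_edf$fs, from_csv$fs, tolerance = 1e-9)
  span <- max(abs(rec$samples))
  expect_lt(max(abs(from_edf$samples - from_csv$samples)), span / 1e4)
})

test_that("band-pass attenuation matches the designed filter response", {
  fs <- 128
  flt <- signal::butter(4, c(0.5, 45) * 2 / fs, type = "pass")
  x <- make_tone(50, fs, secs = 20)
  rec <- recording(matrix(x, 1), fs, "ch1", modality = "COE")
  y <- bandpass(rec, 0.5, 45)$samples[1, ]
  idx <- 500:(length(x) - 500)  # avoid start-up transients
  measured <- sqrt(mean(y[idx]^2)) / sqrt(mean(x[idx]^2))
  predicted <- filter_gain(flt, 50, fs)^2  # forward-backward squares gain
  expect_lt(measured, 0.1)
  expect_equal(measured, predicted, tolerance = 0.25)

  # passband tone through its own band is preserved
  x10 <- make_tone(10, fs, secs = 20)
  rec10 <- recording(matrix(x10, 1), fs, "ch1", modality = "COE")
  y10 <- bandpass(rec10, 8, 12)$samples[1, ]
  expect_equal(sqrt(mean(y10[idx]^2)), sqrt(mean(x10[idx]^2)),
               tolerance = 0.05)

  # DC is rejected whenever low > 0 (finite-length roll-off leaves a
  # sub-percent residual away from the edges)
  recc <- recording(matrix(rep(3, fs * 10), 1), fs, "ch1", modality = "COE")
  yc <- bandpass(recc, 0.5, 45)$samples[1, ]
  mid <- 400:(length(yc) - 400)
  expect_lt(max(abs(yc[mid])), 0.01 * 3)

  expect_error(bandpass(rec, 8, 70), "fs/2")
})

test_that("filtering is linear and zero-phase", {
  fs <- 128
  set.seed(71)
  x <- rnorm(fs * 8); y <- rnorm(fs * 8)
  bp <- function(v) bandpass(recording(matrix(v, 1), fs, "c", "COE"),
                             8, 12)$samples[1, ]
  lhs <- bp(2 * x + 3 * y)
  rhs <- 2 * bp(x) + 3 * bp(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)

  tone <- make_tone(10, fs, secs = 8)
  filt <- bp(tone)
  cc <- stats::ccf(filt, tone, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("sub-band decomposition isolates tones and is idempotent per band", {
  fs <- 128
  tones <- c(delta = 2, theta = 6, alpha = 10, beta = 20)
  x <- rowSums(sapply(tones, make_tone, fs = fs, secs = 10))
  rec <- recording(matrix(rep(x, 14), 14, byrow = TRUE), fs, eeg_montage(),
                   modality = "EEG")
  bands <- decompose_bands(rec)
  for (b in names(tones)) {
    r <- eeg_bands()[[b]]
    xb <- bands[[b]]$samples[1, ]
    expect_gt(band_power_fraction(xb, fs, r[1], r[2]), 0.8)
    # dominant periodogram frequency is the band's own tone
    spec <- Mod(stats::fft(xb))^2
    freqs <- (seq_along(spec) - 1) / length(spec) * fs
    expect_equal(freqs[which.max(spec[freqs <= fs / 2])], tones[[b]],
                 tolerance = 0.2)
    # re-filtering a band output barely changes it
    again <- bandpass(bands[[b]], r[1], r[2])$samples[1, ]
    expect_lt(abs(sd(again) - sd(xb)) / sd(xb), 0.01)
  }
  silent <- recording(matrix(0, 14, fs * 5), fs, eeg_montage(), "EEG")
  out <- decompose_bands(silent)
  expect_true(all(vapply(out, function(r) max(abs(r$samples)), 0) < 1e-10))
  coe <- recording(matrix(0, 2, 100), 10, c("a", "b"), "COE")
  expect_error(decompose_bands(coe), "EEG")
})

test_that("cerebral oxygen exchange is the samplewise HbR - HbO difference", {
  fs <- 10
  ch <- fnirs_channels()
  m <- function(v) recording(matrix(v, 6, 100, byrow = TRUE), fs, ch, "HBO")
  hbo <- m(0.5); hbr <- m(2)
  hbr$modality <- "HBR"
  coe <- compute_coe(hbo, hbr)
  expect_true(all(coe$samples == 1.5))
  expect_identical(coe$modality, "COE")

  same <- compute_coe(hbo, { h <- hbo; h$modality <- "HBR"; h })
  expect_true(all(same$samples == 0))

  set.seed(81)
  a <- matrix(rnorm(600), 6); b <- matrix(rnorm(600), 6)
  ra <- recording(a, fs, ch, "HBO"); rb <- recording(b, fs, ch, "HBR")
  expect_equal(compute_coe(ra, rb)$samples, b - a, ignore_attr = TRUE)

  short <- recording(matrix(rnorm(300), 6), fs, ch, "HBR")
  expect_error(compute_coe(hbo, short), "share")
})

test_that("FMS labeling follows the score > 1 dichotomy", {
  expect_identical(label_segment(1), 0L)
  expect_identical(label_segment(2), 1L)
  expect_identical(label_segment(6), 1L)
  expect_error(label_segment(0), "1..6")
  expect_error(label_segment(7), "1..6")
  expect_error(label_segment(2.5), "1..6")
})

test_that("artifact hook is identity by default and enforces its contract", {
  rec <- gen_eeg_segment("NM", tiny_synth_cfg(), seed = 91)
  expect_identical(artifact_hook(rec, "none"), rec)
  expect_identical(artifact_hook(rec, function(r) r)$samples, rec$samples)
  halved <- artifact_hook(rec, function(r) { r$samples <- r$samples / 2; r })
  expect_equal(sqrt(mean(halved$samples^2)),
               sqrt(mean(rec$samples^2)) / 2, tolerance = 1e-12)
  expect_error(
    artifact_hook(rec, function(r) { r$samples <- r$samples[, 1:10]; r }),
    "shape"
  )
})
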