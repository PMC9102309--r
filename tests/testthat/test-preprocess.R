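test_that("downsampling by an integer factor keeps length arithmetic and DC", {
  r <- recording(sin(2 * pi * 5 * (0:18431) / 2048), fs = 2048)
  d <- downsample(r, 256)
  expect_equal(d$fs, 256)
  expect_length(d$samples, 2304L)  # 18432 / 8
  rc <- recording(rep(3.5, 4096), fs = 2048)
  dc <- downsample(rc, 256)
  expect_lt(max(abs(dc$samples - 3.5)), 1e-6)
})

test_that("downsampling preserves in-band amplitude and rejects aliasing", {
  t <- (0:65535) / 2048
  r <- recording(sin(2 * pi * 5 * t), fs = 2048)
  d <- downsample(r, 256)
  core <- d$samples[100:(length(d$samples) - 100)]  # ignore edge taper
  expect_lt(abs(max(abs(core)) - 1), 0.01)          # 5 Hz << 128 Hz Nyquist
  # a 200 Hz tone lies above the target Nyquist and must be attenuated
  # >= 60 dB; measured over the record interior (boundary-reflection
  # transients are confined to ~a filter settle time at the two edges)
  ra <- recording(sin(2 * pi * 200 * t), fs = 2048)
  da <- downsample(ra, 256)
  core <- da$samples[129:(length(da$samples) - 128)]  # drop 0.5 s per edge
  att <- sqrt(mean(core^2)) / sqrt(mean(ra$samples^2))
  expect_lt(20 * log10(att), -60)
  # even including the edges the residue stays far below the signal
  att_all <- sqrt(mean(da$samples^2)) / sqrt(mean(ra$samples^2))
  expect_lt(20 * log10(att_all), -40)
  expect_error(downsample(d, 2048), "upsampling")
  expect_error(downsample(d, 0), "positive")
})

test_that("notch filtering attenuates the power line and its in-band harmonics", {
  t <- (0:8191) / 256
  cfg <- preprocess_config()
  for (f0 in c(50, 100)) {  # harmonics below the 128 Hz Nyquist
    r <- recording(sin(2 * pi * f0 * t), fs = 256)
    y <- notch_filter(r, cfg)
    expect_length(y$samples, length(r$samples))
    expect_lt(sqrt(mean(y$samples^2)), 0.1 * sqrt(mean(r$samples^2)))
  }
  # content away from the notches passes through
  r <- recording(sin(2 * pi * 30 * t), fs = 256)
  y <- notch_filter(r, cfg)
  expect_gt(sqrt(mean(y$samples^2)), 0.95 * sqrt(mean(r$samples^2)))
})

test_that("notch at or above Nyquist is skipped with a warning (25 Hz fNIRS)", {
  r <- recording(stats::rnorm(500), fs = 25, modality = "fNIRS")
  expect_warning(y <- notch_filter(r, preprocess_config()), "Nyquist")
  expect_identical(y$samples, r$samples)
})

test_that("polynomial baseline correction removes fitted trends", {
  ramp <- recording(seq(0, 5, length.out = 1000), fs = 100)
  out <- baseline_correct(ramp, 1)
  expect_lt(max(abs(out$samples)), 1e-8)

  set.seed(1)
  x <- stats::rnorm(1000)
  out0 <- baseline_correct(recording(x, 100), 0)
  expect_equal(out0$samples, x - mean(x), tolerance = 1e-12)

  # cubic trend under a sinusoid: residual trend energy < 1% of the trend
  t <- seq(-1, 1, length.out = 2000)
  trend <- 3 * t^3 - 2 * t^2 + t
  sig <- sin(2 * pi * 8 * seq(0, 10, length.out = 2000))
  out3 <- baseline_correct(recording(sig + trend, 200), 3)
  resid_trend <- out3$samples - sig
  expect_lt(mean(resid_trend^2) / mean(trend^2), 0.01)

  expect_error(baseline_correct(recording(1:10, 10), 20), "smaller")
})

test_that("preprocessing is linear and preserves bookkeeping", {
  set.seed(2)
  x <- stats::rnorm(4096)
  cfg <- preprocess_config(target_fs = 256, baseline_poly_order = 4)
  r1 <- preprocess_recording(recording(x, 2048), cfg)
  r2 <- preprocess_recording(recording(3 * x, 2048), cfg)
  expect_equal(r2$samples, 3 * r1$samples, tolerance = 1e-9)
  expect_equal(r1$fs, 256)
  expect_true(all(is.finite(r1$samples)))
})

test_that("both channels of a pair are preprocessed identically", {
  cfg <- small_eeg_config(seed = 5)
  pair <- generate_paired(cfg)
  pp <- preprocess_pair(pair, preprocess_config(baseline_poly_order = 2))
  solo <- preprocess_recording(pair$reference, preprocess_config(baseline_poly_order = 2))
  expect_equal(pp$reference$samples, solo$samples)
  expect_equal(pp$artifact_epochs, pair$artifact_epochs)
})
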