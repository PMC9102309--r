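test_that("recording and paired_recording enforce their invariants", {
  expect_error(recording(c(1, NA, 3), 10), "finite")
  expect_error(recording(5, 10), "length")
  expect_error(recording(1:10, -1), "positive")
  r <- recording(1:10, fs = 5, modality = "fNIRS", label = "x")
  expect_equal(duration(r), 2)
  a <- recording(1:10, 10)
  b <- recording(1:9, 10)
  expect_error(paired_recording(a, b), "equal length")
  expect_error(paired_recording(a, recording(1:10, 20)), "sampling rate")
  expect_error(paired_recording(a, a, artifact_epochs = rbind(c(0, 0.5), c(0.4, 0.9))),
               "overlap")
  expect_error(paired_recording(a, a, artifact_epochs = c(0.5, 2)), "within")
  p <- paired_recording(a, a, artifact_epochs = rbind(c(0.1, 0.3), c(0.5, 0.8)))
  expect_equal(sum(artifact_mask(p)), sum((0:9) / 10 >= 0.1 & (0:9) / 10 < 0.3) +
                 sum((0:9) / 10 >= 0.5 & (0:9) / 10 < 0.8))
})

test_that("read_paired_csv parses a minimal identity pair", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("corrupted,reference", "1,1", "2,2", "3,3"), path)
  p <- read_paired_csv(path, fs = 10, modality = "EEG")
  expect_s3_class(p, "paired_recording")
  expect_length(p$corrupted$samples, 3L)
  expect_equal(duration(p$corrupted), 0.3)
})

test_that("read_paired_csv rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("corrupted,reference", "1,1", "2,"), path)  # short reference
  expect_error(read_paired_csv(path, 10, "EEG"), "unparseable|missing")
  writeLines(c("corrupted,reference", "1,1", "2,x"), path)
  expect_error(read_paired_csv(path, 10, "EEG"), "numeric")
  writeLines(c("corrupted,other", "1,1"), path)
  expect_error(read_paired_csv(path, 10, "EEG"), "reference")
  # time column inconsistent with fs
  writeLines(c("time,corrupted,reference", "0,1,1", "0.5,2,2", "1,3,3"), path)
  expect_error(read_paired_csv(path, 10, "EEG"), "time")
  # consistent time column is accepted
  writeLines(c("time,corrupted,reference", "0,1,1", "0.1,2,2", "0.2,3,3"), path)
  expect_length(read_paired_csv(path, 10, "EEG")$corrupted$samples, 3L)
})

test_that("write/read round trip preserves samples and metadata", {
  cfg <- synth_config("EEG", duration_s = 125, fs = 64, seed = 3)
  pair <- generate_paired(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_csv(pair, path)
  back <- read_paired_csv(path, fs = 64, modality = "EEG")
  expect_lt(max(abs(back$corrupted$samples - pair$corrupted$samples)), 1e-9)
  expect_lt(max(abs(back$reference$samples - pair$reference$samples)), 1e-9)
  expect_equal(back$artifact_epochs, pair$artifact_epochs,
               tolerance = 1e-12, ignore_attr = TRUE)
  # empty epochs serialize to an empty list in the sidecar
  pair0 <- paired_recording(pair$corrupted, pair$reference)
  write_paired_csv(pair0, path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_length(meta$artifact_epochs, 0L)
})

test_that("a 540 s pair at 256 Hz writes 138240 data rows", {
  cfg <- synth_config("EEG", duration_s = 540, fs = 256, seed = 1)
  pair <- generate_paired(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_paired_csv(pair, path)
  n_lines <- length(readLines(path))
  expect_equal(n_lines - 1L, 540L * 256L)  # 138240 plus a header
})

test_that("metrics reports serialize losslessly, with batch averaging", {
  rep1 <- metrics_report(6.02, 57.14, 0.6, 0.8, "WPD(db1)")
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep1, path)
  back <- read_metrics_json(path)
  expect_equal(back$delta_snr_db, 6.02, tolerance = 1e-12)
  expect_equal(round(back$delta_snr_db, 2), 6.02)
  expect_equal(back$method, "WPD(db1)")
  # batch: arithmetic mean of each numeric field
  reps <- list(metrics_report(10, 40, 0.5, 0.7, "a"),
               metrics_report(20, 50, 0.6, 0.8, "b"),
               metrics_report(30, 90, 0.7, 0.9, "c"))
  write_metrics_json(reps, path)
  b <- read_metrics_json(path)
  expect_equal(b$summary$delta_snr_db, 20)
  expect_equal(b$summary$eta_pct, 60)
  expect_length(b$reports, 3L)
})
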