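test_that("CSV recordings round-trip bit-identically", {
  set.seed(1)
  rec <- recording("s1", 1, c("Fp1", "Fp2", "Cz"), 250,
                   matrix(rnorm(3 * 500), 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording(path, label = 1, format = "csv", subject_id = "s1")
  expect_identical(dim(back$data), dim(rec$data))
  expect_equal(unname(back$data), unname(rec$data), tolerance = 0)
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$fs, 250)
  expect_identical(back$label, 1L)
})

test_that("transposed CSV layout reads the same matrix", {
  set.seed(2)
  x <- matrix(rnorm(2 * 100), 2, dimnames = list(c("A", "B"), NULL))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(t(x)), path, row.names = FALSE)
  rec <- read_recording(path, label = 0, format = "csv", fs = 100,
                        transposed = TRUE)
  expect_equal(unname(rec$data), unname(x))
  expect_identical(rec$channel_names, c("A", "B"))
})

test_that("recording validation rejects degenerate inputs", {
  expect_error(recording("s", 0, c("a", "a"), 100, matrix(0, 2, 10)),
               "unique")
  expect_error(recording("s", 0, c("a", "b"), -1, matrix(0, 2, 10)), "fs")
  expect_error(recording("s", 2, c("a", "b"), 100, matrix(0, 2, 10)),
               "label")
  expect_error(recording("s", 0, c("a", "b"), 100,
                         matrix(c(NA, 0, 0, 0), 2)), "missing")
  # single-channel file refused by the reader
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs=100", "channel,s1,s2", "only,1,2"), path)
  expect_error(read_recording(path, label = 0), "at least 2")
  expect_error(read_recording("/no/such/file.csv", label = 0), "not found")
})

test_that("synthetic EDF files read back with correct labels, fs and data", {
  set.seed(3)
  x <- matrix(rnorm(3 * 500, sd = 20), 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_minimal(path, x, fs = 250,
                    labels = c("EEG Fp1-REF", "EEG Fp2-REF", "Cz"))
  rec <- suppressMessages(
    read_recording(path, label = 1, format = "edf", subject_id = "p1"))
  expect_identical(rec$channel_names, c("Fp1", "Fp2", "Cz"))
  expect_identical(rec$fs, 250)
  expect_equal(unname(rec$data), edf_quantize(x), tolerance = 1e-8)
  # reference-suffix stripping is reported
  expect_message(read_recording(path, label = 1, format = "edf"),
                 "Fp1")
})

test_that("band-limiting attenuates out-of-band tones and keeps in-band ones", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)[-1]
  power_at <- function(x, f) {
    sp <- Mod(fft(x))^2
    sp[round(f * length(x) / fs) + 1]
  }
  mk <- function(freq) recording("s", 0, c("a", "b"), fs,
                                 rbind(sin(2 * pi * freq * t),
                                       cos(2 * pi * freq * t)))
  # forward-backward order-4 Butterworth: ~19 dB measured at 60 Hz; a
  # numerically verified floor of 15 dB leaves margin
  hi <- bandlimit(mk(60), 0.5, 50, order = 4)
  atten_db <- 10 * log10(power_at(mk(60)$data[1, ], 60) /
                           power_at(hi$data[1, ], 60))
  expect_gt(atten_db, 15)

  lo <- bandlimit(mk(10), 0.5, 50, order = 4)
  ratio <- sqrt(power_at(lo$data[1, ], 10) / power_at(mk(10)$data[1, ], 10))
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)

  z <- bandlimit(recording("s", 0, c("a", "b"), fs, matrix(0, 2, 1000)),
                 0.5, 50)
  expect_true(all(z$data == 0))
  expect_error(bandlimit(mk(10), 50, 0.5), "cutoffs")
  expect_error(bandlimit(mk(10), 0.5, 200), "cutoffs")
})

test_that("band-limiting is nearly idempotent on band-limited noise", {
  set.seed(4)
  raw <- recording("s", 0, c("a1", "a2"), 250, matrix(rnorm(2 * 5000), 2))
  # noise confined well inside the 0.5-50 Hz passband, where the filter
  # gain is flat; repeated filtering should then change almost nothing
  inband <- bandlimit(raw, 2, 20, order = 4)
  once <- bandlimit(inband)
  twice <- bandlimit(once)
  rel <- sqrt(mean((twice$data - once$data)^2)) / sqrt(mean(once$data^2))
  expect_lt(rel, 0.01)
})

test_that("segmentation obeys the window and overlap arithmetic", {
  fs <- 250
  rec12 <- recording("s", 0, c("a", "b"), fs, matrix(0, 2, 12 * 60 * fs))
  expect_length(segment_recording(rec12, 60, 0), 12)

  rec90 <- recording("s", 0, c("a", "b"), fs, matrix(0, 2, 90 * fs))
  expect_length(segment_recording(rec90, 60, 0), 1)

  rec120 <- recording("s", 1, c("a", "b"), fs, matrix(0, 2, 120 * fs))
  segs <- segment_recording(rec120, 60, 0.5)
  expect_length(segs, 3)
  expect_identical(vapply(segs, `[[`, 0L, "segment_index"), 0:2)
  expect_true(all(vapply(segs, `[[`, 0L, "label") == 1L))

  short <- recording("s", 0, c("a", "b"), fs, matrix(0, 2, 30 * fs))
  expect_warning(out <- segment_recording(short, 60, 0), "shorter")
  expect_length(out, 0)
})

test_that("non-overlapping segments exactly partition the used samples", {
  set.seed(5)
  fs <- 100
  rec <- recording("s", 0, c("a", "b", "c"), fs,
                   matrix(rnorm(3 * 2550), 3))   # 25.5 s -> 5 windows of 5 s
  segs <- segment_recording(rec, 5, 0)
  expect_length(segs, 5)
  glued <- do.call(cbind, lapply(segs, `[[`, "data"))
  expect_identical(unname(glued), unname(rec$data[, 1:2500]))
})

test_that("cohort manifests drive batch loading", {
  dir <- withr::local_tempdir()
  set.seed(6)
  for (i in 1:2) {
    rec <- recording(sprintf("S%d", i), i - 1, c("a", "b"), 100,
                     matrix(rnorm(2 * 200), 2))
    write_recording_csv(rec, file.path(dir, sprintf("S%d.csv", i)))
  }
  utils::write.csv(data.frame(subject_id = c("S1", "S2"),
                              path = c("S1.csv", "S2.csv"),
                              label = c(0, 1)),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  recs <- read_cohort(file.path(dir, "manifest.csv"))
  expect_length(recs, 2)
  expect_identical(recs[[2]]$label, 1L)
  expect_identical(recs[[1]]$subject_id, "S1")
})
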