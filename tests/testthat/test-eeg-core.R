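test_that("CSV recordings are read, validated and canonically ordered", {
  tmp <- withr::local_tempdir()
  set.seed(1)
  mat <- matrix(rnorm(19 * 256), ncol = 19)
  colnames(mat) <- eeg_channels_1020
  f <- file.path(tmp, "rec.csv")
  write.csv(mat, f, row.names = FALSE)
  rec <- read_eeg(f, fs = 256)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(dim(rec), c(19L, 256L))
  expect_equal(rec$channels, eeg_channels_1020)
  expect_equal(ncol(rec$data) / rec$fs, 1)

  # scrambled column order comes back canonical
  perm <- sample(19)
  scr <- mat[, perm]
  colnames(scr) <- eeg_channels_1020[perm]
  f2 <- file.path(tmp, "scrambled.csv")
  write.csv(scr, f2, row.names = FALSE)
  rec2 <- read_eeg(f2, fs = 256)
  expect_equal(rec2$channels, eeg_channels_1020)
  expect_equal(rec2$data, rec$data)

  # validation failures
  bad <- as.data.frame(mat)
  bad[3, 2] <- "oops"
  f3 <- file.path(tmp, "bad.csv")
  write.csv(bad, f3, row.names = FALSE)
  expect_error(read_eeg(f3, fs = 256), "non-numeric")
  expect_error(read_eeg(f, format = "csv"), "fs")
})

test_that("recording construction enforces its invariants", {
  expect_error(eeg_recording(matrix(1, 2, 4), fs = 0, channels = c("a", "b")),
               "fs")
  expect_error(eeg_recording(matrix(c(1, NA), 1, 2), fs = 1, channels = "a"),
               "finite")
  expect_error(eeg_recording(matrix(1, 2, 2), fs = 1, channels = c("a", "a")),
               "unique")
  expect_error(eeg_recording(matrix(1, 2, 2), fs = 1, channels = "a"),
               "does not match")
})

test_that("CSV and EDF round trips preserve the signal", {
  tmp <- withr::local_tempdir()
  rec <- make_test_segment(seed = 7, duration_s = 2, fs = 128)
  fc <- file.path(tmp, "rt.csv")
  write_eeg(rec, fc)
  back <- read_eeg(fc, fs = rec$fs)
  expect_equal(back$data, rec$data, tolerance = 1e-6)

  fe <- file.path(tmp, "rt.edf")
  write_eeg(rec, fe)
  backe <- read_eeg(fe)
  expect_equal(backe$fs, rec$fs)
  expect_equal(backe$channels, rec$channels)
  # 16-bit quantisation over the per-channel dynamic range
  qstep <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  expect_true(all(abs(backe$data - rec$data) <= 2 * qstep + 1e-9))
})

test_that("band-pass filter passes in-band and rejects out-of-band tones", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  rec10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, channels = "Cz")
  out10 <- bandpass_filter(rec10)
  expect_equal(sqrt(mean(out10$data^2)), sqrt(mean(rec10$data^2)),
               tolerance = 0.05)

  rec60 <- eeg_recording(matrix(sin(2 * pi * 60 * t), 1), fs, channels = "Cz")
  out60 <- bandpass_filter(rec60)
  expect_lt(sqrt(mean(out60$data^2)), 0.1 * sqrt(mean(rec60$data^2)))

  zero <- eeg_recording(matrix(0, 1, 8 * fs), fs, channels = "Cz")
  expect_equal(bandpass_filter(zero)$data, zero$data)

  expect_error(bandpass_filter(rec10, hi = 130), "Nyquist")
})

test_that("filtering a pass-band signal twice is close to filtering once", {
  fs <- 256
  t <- (0:(8 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 5 * t)
  rec <- eeg_recording(matrix(x, 1), fs, channels = "Cz")
  once <- bandpass_filter(rec)
  twice <- bandpass_filter(once)
  mid <- (2 * fs):(6 * fs)  # compare away from edge transients
  expect_equal(twice$data[1, mid], once$data[1, mid], tolerance = 1e-2)
})

test_that("segmentation arithmetic, inheritance and remainders are exact", {
  fs <- 256
  rec <- eeg_recording(matrix(rnorm(19 * 120 * fs), 19), fs,
                       subject_id = "S9", label = "MCI")
  segs <- segment(rec, 60)
  expect_length(segs, 2)
  expect_true(all(vapply(segs, function(s) ncol(s$data), 0L) == 15360L))
  expect_true(all(vapply(segs, function(s) s$label, "") == "MCI"))
  expect_true(all(vapply(segs, function(s) s$subject_id, "") == "S9"))
  # concatenation reproduces the input
  expect_equal(do.call(cbind, lapply(segs, function(s) s$data)), rec$data)

  rec90 <- eeg_recording(rec$data[, 1:(90 * fs)], fs)
  expect_length(segment(rec90, 60), 1)
  rec59 <- eeg_recording(rec$data[, 1:(59 * fs)], fs)
  expect_warning(empty <- segment(rec59, 60), "shorter")
  expect_length(empty, 0)
})
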