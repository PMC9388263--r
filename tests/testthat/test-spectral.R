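trapz_psd <- function(p) {
  sum(diff(p$freqs) * (head(p$psd, -1) + tail(p$psd, -1)) / 2)
}

test_that("Welch PSD integrates to the signal variance (Parseval)", {
  fs <- 256
  t <- (0:(60 * fs - 1)) / fs
  p <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(trapz_psd(p), 0.5, tolerance = 0.02)

  w <- withr::with_seed(2, rnorm(60 * fs, sd = 2))
  pw <- welch_psd(w, fs)
  expect_equal(trapz_psd(pw), 4, tolerance = 0.05)

  pz <- welch_psd(numeric(60 * fs), fs)
  expect_true(all(pz$psd == 0))

  expect_error(welch_psd(rnorm(100), fs, win_len = 512), "win_len")
})

test_that("band power concentrates where the tone lives", {
  fs <- 256
  t <- (0:(60 * fs - 1)) / fs
  p <- welch_psd(sin(2 * pi * 10 * t), fs)
  total <- trapz_psd(p)
  expect_equal(band_power(p, 8, 13), total, tolerance = 0.02)
  expect_lt(band_power(p, 4, 8), 0.01 * total)
  expect_lt(band_power(p, 13, 32), 0.01 * total)

  p2 <- welch_psd(sin(2 * pi * 6 * t) + sin(2 * pi * 20 * t), fs)
  expect_equal(band_power(p2, 4, 8), band_power(p2, 13, 32),
               tolerance = 0.05)

  expect_equal(band_power(welch_psd(numeric(fs * 4), fs, 512), 8, 13), 0)
  expect_error(band_power(p, 100, 200), "outside")
})

test_that("interhemispheric asymmetry is a natural-log antisymmetric ratio", {
  expect_equal(interhemispheric_asymmetry(3, 3), 0)
  expect_equal(interhemispheric_asymmetry(exp(1) * 2, 2), 1)
  expect_equal(interhemispheric_asymmetry(5, 2),
               -interhemispheric_asymmetry(2, 5))
  expect_error(interhemispheric_asymmetry(0, 1), "positive")
})

test_that("spectral feature vector has the 76 + 32 = 108 layout", {
  seg <- make_test_segment(seed = 11, duration_s = 4, fs = 128)
  v <- spectral_features(seg)
  expect_length(v, 108)
  expect_equal(sum(startsWith(names(v), "bp_")), 4 * 19)
  expect_equal(sum(startsWith(names(v), "ia_")), 4 * 8)
  expect_identical(v, spectral_features(seg))  # deterministic
  expect_true(all(v[startsWith(names(v), "bp_")] >= 0))
})

test_that("amplitude scaling moves band powers by c^2 and leaves IA fixed", {
  seg <- make_test_segment(seed = 12, duration_s = 4, fs = 128)
  v1 <- spectral_features(seg)
  seg2 <- seg
  seg2$data <- 3 * seg$data
  v2 <- spectral_features(seg2)
  bp <- startsWith(names(v1), "bp_")
  expect_equal(v2[bp], 9 * v1[bp], tolerance = 1e-10)
  expect_equal(v2[!bp], v1[!bp], tolerance = 1e-10)
})

test_that("four-band powers never exceed the total integrated PSD", {
  seg <- make_test_segment(seed = 13, duration_s = 4, fs = 128)
  x <- seg$data[1, ]
  p <- welch_psd(x, seg$fs)
  total <- trapz_psd(p)
  bands <- eeg_bands()
  bsum <- sum(vapply(seq_len(nrow(bands)),
                     function(i) band_power(p, bands$lo[i], bands$hi[i]), 0))
  expect_lte(bsum, total + 1e-9)
})
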