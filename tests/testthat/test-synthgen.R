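test_that("cohort generation is bit-identical under a fixed seed", {
  spec <- cohort_spec(n_mci = 2, n_hc = 1, duration_s = 2, fs = 128, seed = 5)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a, b)
  expect_equal(vapply(a, function(r) r$label, ""), c("MCI", "MCI", "HC"))
  expect_equal(dim(a[[1]]), c(19L, 256L))
})

test_that("known signal generators match their defining recursions", {
  # logistic map iterates x_{n+1} = r x_n (1 - x_n)
  lg <- gen_known_signal("logistic_map", 6, x0 = 0.3)
  manual <- Reduce(function(x, i) 4 * x * (1 - x), 1:5, accumulate = TRUE,
                   init = 0.3)
  expect_equal(lg, manual, tolerance = 1e-12)
  expect_equal(lg[2:6], c(0.84, 0.5376, 0.99434496, 0.02249224, 0.08794538),
               tolerance = 1e-7)

  expect_identical(gen_known_signal("constant", 10, value = 2), rep(2, 10))
  expect_identical(gen_known_signal("impulse", 5), c(1, 0, 0, 0, 0))

  w <- gen_known_signal("white", 10000, seed = 6, sd = 2)
  expect_equal(mean(w), 0, tolerance = 0.1)
  expect_equal(var(w), 4, tolerance = 0.2)

  expect_identical(gen_known_signal("henon_map", 100),
                   gen_known_signal("henon_map", 100))
  expect_error(gen_known_signal("logistic_map", 10, x0 = 2), "x0")
})

test_that("fixture directories round-trip through the manifest", {
  tmp <- withr::local_tempdir()
  spec <- cohort_spec(n_mci = 2, n_hc = 2, duration_s = 2, fs = 128, seed = 9)
  recs <- gen_cohort(spec)
  write_fixtures(recs, tmp)
  files <- list.files(tmp)
  expect_length(files, 5)   # 4 signals + manifest
  back <- read_fixtures(tmp)
  expect_length(back, 4)
  expect_equal(back[[1]]$data, recs[[1]]$data, tolerance = 1e-6)
  expect_equal(vapply(back, function(r) r$label, ""),
               vapply(recs, function(r) r$label, ""))
})

test_that("generated band powers scale as amplitude squared", {
  base <- c(delta = 2, theta = 2, alpha = 6, beta = 2)
  mk <- function(alpha_amp) {
    amps <- base; amps["alpha"] <- alpha_amp
    spec <- cohort_spec(n_mci = 1, n_hc = 1, duration_s = 8, fs = 128,
                        band_amp = list(HC = amps, MCI = amps),
                        coupling = list(HC = 0, MCI = 0),
                        noise_amp = 0.5, seed = 77)
    mean(spectral_features(gen_cohort(spec)[[1]])[
      paste0("bp_alpha_", eeg_channels_1020)])
  }
  expect_equal(mk(6) / mk(3), 4, tolerance = 0.15)
})

test_that("a group alpha deficit is recovered as a significant difference", {
  spec <- cohort_spec(
    n_mci = 15, n_hc = 15, duration_s = 8, fs = 128,
    band_amp = list(HC = c(delta = 4, theta = 5, alpha = 10, beta = 5),
                    MCI = c(delta = 4, theta = 5, alpha = 5, beta = 5)),
    coupling = list(HC = 0, MCI = 0), seed = 21)
  ft <- assemble_features(gen_cohort(spec), sets = "spectral")
  tt <- ttest_features(ft, subset = paste0("bp_alpha_", c("O1", "O2", "Pz")))
  expect_true(all(tt$p < 0.01))
  # MCI group mean alpha power is the lower one
  mci <- ft$label == "MCI"
  expect_lt(mean(ft$bp_alpha_O1[mci]), mean(ft$bp_alpha_O1[!mci]))
})

test_that("null cohorts produce no systematic group differences", {
  spec <- cohort_spec(n_mci = 10, n_hc = 10, duration_s = 4, fs = 128,
                      coupling = list(HC = 0.3, MCI = 0.3),
                      band_amp = list(
                        HC = c(delta = 4, theta = 5, alpha = 10, beta = 5),
                        MCI = c(delta = 4, theta = 5, alpha = 10, beta = 5)),
                      seed = 31)
  ft <- assemble_features(gen_cohort(spec), sets = "spectral")
  tt <- ttest_features(ft)
  expect_lt(mean(tt$p < 0.05), 0.25)   # near the nominal type-I rate
})
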