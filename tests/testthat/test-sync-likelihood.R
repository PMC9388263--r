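test_that("time-delay embedding follows the index arithmetic", {
  x <- 1:10
  v <- embed_delay(x, m = 3, l = 2)
  expect_equal(dim(v), c(6L, 3L))
  expect_equal(v[1, ], c(1, 3, 5))
  expect_equal(v[6, ], c(6, 8, 10))

  v1 <- embed_delay(x, m = 1, l = 5)
  expect_equal(as.numeric(v1), as.numeric(x))

  vc <- embed_delay(rep(2, 12), m = 4, l = 2)
  expect_true(all(apply(vc, 1, function(r) all(r == 2))))

  expect_error(embed_delay(1:5, m = 3, l = 3), "too short")
})

test_that("critical distance is the p_ref-quantile rank statistic", {
  set.seed(5)
  v <- embed_delay(rnorm(200), m = 2, l = 1)
  # tiny p_ref: distance to the single nearest valid neighbor
  i <- 100
  d_all <- sqrt(colSums((t(v) - v[i, ])^2))
  valid <- abs(seq_len(nrow(v)) - i) > 5 & abs(seq_len(nrow(v)) - i) < 60
  expect_equal(critical_distance(v, i, p_ref = 1e-6, w1 = 5, w2 = 60),
               min(d_all[valid]))
  # ties: all pairwise distances equal
  vt <- embed_delay(rep(c(0, 1), 30), m = 2, l = 2)[seq(1, 57, by = 2), ]
  d <- sqrt(sum((vt[1, ] - vt[2, ])^2))
  expect_equal(critical_distance(vt, 5, p_ref = 0.3, w1 = 1, w2 = 20), d)
  # monotone in p_ref
  eps <- vapply(c(0.05, 0.2, 0.5, 0.9),
                function(p) critical_distance(v, i, p, 5, 60), 0)
  expect_false(is.unsorted(eps))
  expect_error(critical_distance(v, 1, 0.05, w1 = 500, w2 = 600), "valid")
})

test_that("identical signals give likelihood exactly 1", {
  x <- gen_known_signal("pink", 1500, seed = 3)
  expect_identical(sync_likelihood_pair(x, x), 1)
})

test_that("likelihood is symmetric, bounded and affine invariant", {
  p <- sl_params()
  x <- gen_known_signal("pink", 1200, seed = 4)
  y <- gen_known_signal("pink", 1200, seed = 5)
  sxy <- sync_likelihood_pair(x, y, p)
  expect_identical(sxy, sync_likelihood_pair(y, x, p))
  expect_gte(sxy, 0); expect_lte(sxy, 1)
  # per-channel affine rescaling cannot change the rank-statistic recurrences
  expect_equal(sync_likelihood_pair(3.7 * x + 11, -0 + 0.2 * y, p), sxy)
})

test_that("likelihood rises monotonically with shared-signal mixing", {
  p <- sl_params()
  x <- gen_known_signal("pink", 2000, seed = 6)
  n <- gen_known_signal("white", 2000, seed = 7)
  s <- vapply(c(0, 0.5, 1),
              function(c) sync_likelihood_pair(x, (1 - c) * n + c * x, p), 0)
  expect_false(is.unsorted(s))
  expect_identical(s[3], 1)
  expect_lt(s[1], 0.05)
})

test_that("a lagged copy with matched embedding lag is strongly synchronized", {
  p <- sl_params()
  a <- gen_known_signal("pink", 2010, seed = 9)
  expect_gt(sync_likelihood_pair(a[11:2010], a[1:2000], p), 0.5)
})

test_that("the pairwise SL matrix yields 171 named features", {
  # all channels identical copies: every entry exactly 1, cheap to compute
  x <- gen_known_signal("pink", 700, seed = 10)
  seg <- eeg_recording(matrix(rep(x, 19), nrow = 19, byrow = TRUE), fs = 128)
  m <- sl_matrix(seg)
  v <- connectivity_features(seg)
  expect_length(v, 171)
  expect_true(all(v == 1))
  expect_true(all(is.na(diag(m$values))))
  expect_equal(m$values, t(m$values))
  expect_equal(names(v)[1], "sl_Fp1-Fp2")

  # channel-permutation invariance after canonical reordering
  perm <- withr::with_seed(1, sample(19))
  seg2 <- eeg_recording(seg$data[perm, ], fs = 128,
                        channels = seg$channels[perm])
  expect_identical(connectivity_features(seg2), v)

  df <- tidy(m)
  expect_equal(nrow(df), 171)
  expect_true(all(df$sl == 1))
})
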