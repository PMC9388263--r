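test_that("DFA recovers the theoretical exponents of noise classes", {
  expect_equal(dfa(gen_known_signal("white", 4096, seed = 3)), 0.5,
               tolerance = 0.1)
  expect_equal(dfa(gen_known_signal("brownian", 4096, seed = 3)), 1.5,
               tolerance = 0.1)
  expect_error(dfa(rep(1, 1000)), "constant")
})

test_that("Higuchi dimension is exact for a line and ~2 for white noise", {
  expect_equal(higuchi_fd(as.numeric(1:4096)), 1, tolerance = 1e-8)
  expect_equal(higuchi_fd(gen_known_signal("white", 4096, seed = 4)), 2,
               tolerance = 0.1)
  expect_lte(higuchi_fd(gen_known_signal("sine", 4096, period = 128)), 1.2)
  expect_error(higuchi_fd(rep(0, 4096)), "constant")
})

test_that("correlation dimension matches known attractor geometries", {
  hn <- gen_known_signal("henon_map", 5000)
  expect_equal(correlation_dimension(hn, tau = 1, m_max = 6), 1.22,
               tolerance = 0.15)
  circ <- gen_known_signal("sine", 4096, period = 256) +
    0.01 * gen_known_signal("white", 4096, seed = 7)
  expect_equal(correlation_dimension(circ), 1.0, tolerance = 0.2)
  expect_error(correlation_dimension(rep(2, 2000)), "constant")
})

test_that("largest Lyapunov exponent separates chaos from regularity", {
  lg <- gen_known_signal("logistic_map", 2000)
  expect_equal(largest_lyapunov(lg), log(2), tolerance = 0.10)
  sn <- gen_known_signal("sine", 4096, period = 128)
  expect_lte(largest_lyapunov(sn), 0.05)
})

test_that("C0-complexity separates tones from impulses", {
  s <- gen_known_signal("sine", 1024, period = 64)
  expect_lt(c0_complexity(s), 0.01)
  expect_equal(c0_complexity(gen_known_signal("impulse", 512)), 1)
  for (seed in 1:5) {
    x <- gen_known_signal("white", 500, seed = seed)
    c0 <- c0_complexity(x)
    expect_gte(c0, 0); expect_lte(c0, 1)
  }
  expect_error(c0_complexity(numeric(16)), "all-zero")
})

test_that("K2 entropy is near zero for tones and ln 2 for the logistic map", {
  expect_lte(kolmogorov_entropy(gen_known_signal("sine", 4096, period = 128)),
             0.05)
  lg <- gen_known_signal("logistic_map", 5000)
  expect_equal(kolmogorov_entropy(lg, m = 2, tau = 1), log(2),
               tolerance = 0.2)
})

test_that("Shannon entropy hits its closed-form bounds", {
  expect_equal(shannon_entropy(rep(5, 100)), 0)
  expect_equal(shannon_entropy(rep(1:16, each = 10)), log(16))
  for (seed in 1:5) {
    x <- gen_known_signal("white", 400, seed = seed)
    expect_lte(shannon_entropy(x), log(16))
  }
})

test_that("approximate entropy behaves on regular and degenerate inputs", {
  expect_identical(approximate_entropy(rep(3, 300)), 0)
  alt <- rep(c(1, -1), 150)
  expect_lt(approximate_entropy(alt), 0.05)
  expect_error(approximate_entropy(1:100, r = -1), "positive")
})

test_that("closed-formula descriptors match independent brute force to 1e-9", {
  for (seed in 1:10) {
    n <- 200 + 60 * seed   # lengths up to 800
    x <- gen_known_signal("pink", n, seed = seed)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, m = 2, r = r), bf_apen(x, 2, r),
                 tolerance = 1e-9)
    expect_equal(c0_complexity(x), bf_c0(x), tolerance = 1e-9)
    expect_equal(shannon_entropy(x), bf_shannon(x), tolerance = 1e-9)
  }
})

test_that("descriptors are invariant to positive amplitude rescaling", {
  x <- gen_known_signal("pink", 1500, seed = 21)
  a <- 4.2
  expect_equal(dfa(a * x), dfa(x), tolerance = 1e-8)
  expect_equal(higuchi_fd(a * x), higuchi_fd(x), tolerance = 1e-8)
  expect_equal(shannon_entropy(a * x), shannon_entropy(x), tolerance = 1e-12)
  expect_equal(approximate_entropy(a * x), approximate_entropy(x),
               tolerance = 1e-8)
  expect_equal(c0_complexity(a * x), c0_complexity(x), tolerance = 1e-12)
  expect_equal(correlation_dimension(a * x), correlation_dimension(x),
               tolerance = 1e-6)
})

test_that("approximate entropy orders sine < sine+noise < noise", {
  s <- gen_known_signal("sine", 1000, period = 50)
  w <- gen_known_signal("white", 1000, seed = 22, sd = 0.5)
  a1 <- approximate_entropy(s)
  a2 <- approximate_entropy(s + w)
  a3 <- approximate_entropy(gen_known_signal("white", 1000, seed = 23))
  expect_lt(a1, a2)
  expect_lt(a2, a3)
})

test_that("the nonlinear feature vector has the 8 x 19 = 152 layout", {
  seg <- make_test_segment(seed = 31, duration_s = 4, fs = 128)
  v <- nonlinear_features(seg)
  expect_length(v, 152)
  expect_equal(sum(startsWith(names(v), "dfa_")), 19)
  expect_true(all(is.finite(v)))

  # identical channels give identical per-descriptor values
  x <- gen_known_signal("pink", 512, seed = 32)
  seg2 <- eeg_recording(matrix(rep(x, 19), 19, byrow = TRUE), fs = 128)
  v2 <- nonlinear_features(seg2)
  for (d in c("dfa", "shannon", "apen")) {
    vals <- v2[startsWith(names(v2), paste0(d, "_"))]
    expect_equal(max(vals) - min(vals), 0)
  }
})
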