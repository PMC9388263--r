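# Independent brute-force oracles, deliberately naive and coded without
# reference to the package implementations.

# Approximate entropy by direct double loops over template vectors
# (Chebyshev distance, self-matches included).
bf_apen <- function(x, m, r) {
  phi <- function(mm) {
    n_vec <- length(x) - mm + 1
    logs <- numeric(n_vec)
    for (i in seq_len(n_vec)) {
      cnt <- 0
      for (j in seq_len(n_vec)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / n_vec)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# C0-complexity via a literal O(N^2) discrete Fourier transform.
bf_c0 <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)
  M <- mean(Mod(X)^2)
  Y <- ifelse(Mod(X)^2 > M, X, 0)
  y <- Re(as.vector(Conj(W) %*% Y) / n)
  sum((x - y)^2) / sum(x^2)
}

# Shannon entropy of the amplitude histogram, naive binning loop.
bf_shannon <- function(x, n_bins = 16) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  counts <- numeric(n_bins)
  for (v in x) {
    b <- floor((v - lo) / (hi - lo) * n_bins) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p))
}

# A small canonical 19-channel synthetic segment for extraction tests.
make_test_segment <- function(seed = 42, duration_s = 6, fs = 128) {
  spec <- cohort_spec(n_mci = 1, n_hc = 1, duration_s = duration_s, fs = fs,
                      seed = seed)
  gen_cohort(spec)[[1]]
}

# Toy feature table: feature f1 separates the classes by +/- `sep`,
# the rest are pure noise.
make_toy_features <- function(n = 200, p = 10, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("MCI", "HC"), each = n / 2)
    X <- matrix(stats::rnorm(n * p), n)
    X[, 1] <- X[, 1] + ifelse(y == "MCI", sep, -sep)
    colnames(X) <- paste0("f", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(subject_id = as.character(seq_len(n)), label = y),
      tibble::as_tibble(X)
    )
  })
}
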