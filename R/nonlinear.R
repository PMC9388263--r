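#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-removed signal into a profile, detrends it piecewise
#' linearly over non-overlapping windows of each scale, and returns the
#' scaling exponent `alpha`: the log-log slope of RMS fluctuation versus
#' window size. White noise gives ~0.5, Brownian motion ~1.5.
#'
#' @param x Numeric signal.
#' @param scales Integer window sizes; default log-spaced from 4 to
#'   `length(x)/4`, at least 10 scales.
#' @return Scalar exponent `alpha`.
#' @export
dfa <- function(x, scales = NULL) {
  n <- length(x)
  if (stats::sd(x) == 0) stop("DFA undefined for a constant signal",
                              call. = FALSE)
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(4), log(n / 4), length.out = 12))))
  }
  scales <- scales[scales >= 4 & scales <= n %/% 2]
  if (length(scales) < 4) stop("need at least 4 usable scales", call. = FALSE)
  prof <- cumsum(x - mean(x))
  f <- vapply(scales, function(s) {
    k <- n %/% s
    res2 <- 0
    t_idx <- seq_len(s)
    for (w in seq_len(k)) {
      seg <- prof[((w - 1) * s + 1):(w * s)]
      fit <- stats::lm.fit(cbind(1, t_idx), seg)
      res2 <- res2 + sum(fit$residuals^2)
    }
    sqrt(res2 / (k * s))
  }, 0)
  unname(stats::coef(stats::lm(log(f) ~ log(scales)))[2])
}

#' Higuchi fractal dimension
#'
#' Builds the `T` decimated sub-curves at each scale `T = t_min..t_max`,
#' averages their normalised lengths, and returns the slope of
#' `ln L(T)` versus `ln(1/T)`. A straight line gives exactly 1; white noise
#' approaches 2.
#'
#' @param x Numeric signal.
#' @param t_min,t_max Scale range in samples (defaults 1 and 30).
#' @return Scalar fractal dimension.
#' @export
higuchi_fd <- function(x, t_min = 1, t_max = 30) {
  n <- length(x)
  stopifnot(t_min >= 1, t_max > t_min)
  if (n <= 2 * t_max) stop("signal too short for the scale range",
                           call. = FALSE)
  if (stats::sd(x) == 0) stop("fractal dimension undefined for a constant signal",
                              call. = FALSE)
  ts <- t_min:t_max
  lt <- vapply(ts, function(tt) {
    lens <- vapply(seq_len(tt), function(tau) {
      nk <- (n - tau) %/% tt
      if (nk < 1) return(NA_real_)
      idx <- tau + (0:nk) * tt
      sum(abs(diff(x[idx]))) * (n - 1) / (nk * tt) / tt
    }, 0)
    mean(lens, na.rm = TRUE)
  }, 0)
  unname(stats::coef(stats::lm(log(lt) ~ log(1 / ts)))[2])
}

# First zero crossing of the autocorrelation, capped; standard delay choice
# for state-space embedding of oscillatory signals.
acf_delay <- function(x, cap = 20) {
  a <- stats::acf(x, lag.max = cap, plot = FALSE)$acf[-1]
  z <- which(a <= 0)
  if (length(z)) z[1] else cap
}

# Log-log slope of the correlation integral over its scaling region,
# selected on the C axis: radii where C_lo <= C(r) <= C_hi. This keeps the
# fit away from both the noise floor (tiny C, inflated slopes) and the
# saturation shoulder near C = 1.
scaling_slope <- function(rs, C, C_lo = 0.01, C_hi = 0.3) {
  ok <- which(C >= C_lo & C <= C_hi)
  if (length(ok) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(log(C[ok]) ~ log(rs[ok])))[2])
}

#' Grassberger-Procaccia correlation dimension
#'
#' Estimates the correlation integral `C_m(r)` over an increasing embedding
#' schedule (Euclidean norm, Theiler exclusion) and reports the saturated
#' log-log slope: the first dimension at which successive slope estimates
#' change by less than `sat_tol`.
#'
#' @param x Numeric signal.
#' @param tau Embedding delay; default from the first autocorrelation zero
#'   (capped at 20).
#' @param m_max Largest embedding dimension in the schedule (default 10).
#' @param theiler Temporal exclusion window in samples (default `tau`).
#' @param max_points Cap on the number of state vectors used in the pair sums
#'   (default 2000; larger inputs are subsampled evenly).
#' @param sat_tol Relative saturation tolerance between successive dimensions
#'   (default 0.05).
#' @return Scalar dimension estimate.
#' @export
correlation_dimension <- function(x, tau = NULL, m_max = 10, theiler = NULL,
                                  max_points = 2000, sat_tol = 0.05) {
  if (stats::sd(x) == 0) stop("correlation dimension undefined for a constant signal",
                              call. = FALSE)
  if (is.null(tau)) tau <- acf_delay(x)
  if (is.null(theiler)) theiler <- tau
  s <- stats::sd(x)
  rs <- s * exp(seq(log(0.005), log(5), length.out = 36))
  C <- corr_sums_cpp(as.numeric(x), tau, m_max, rs, theiler, max_points)
  d_by_m <- vapply(seq_len(m_max), function(m) scaling_slope(rs, C[m, ]), 0)
  d_by_m <- d_by_m[!is.na(d_by_m)]
  if (length(d_by_m) < 2) stop("no usable scaling region", call. = FALSE)
  for (m in 2:length(d_by_m)) {
    if (abs(d_by_m[m] - d_by_m[m - 1]) < sat_tol * abs(d_by_m[m - 1])) {
      return(d_by_m[m])
    }
  }
  d_by_m[length(d_by_m)]
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' For each embedded point, the nearest neighbor outside a temporal exclusion
#' window (the signal's mean period) is followed forward; the exponent is the
#' slope of the initial linear region of the average log-divergence curve,
#' in nats per sample.
#'
#' @param x Numeric signal.
#' @param m Embedding dimension (default 2, suited to low-dimensional maps;
#'   raise for flow data).
#' @param tau Embedding delay (default from the autocorrelation).
#' @param horizon Number of divergence steps to follow (default 20).
#' @param fit_range Integer steps over which to fit the slope; default
#'   automatic (from step 1 up to where the curve has risen to 60% of its
#'   total span, ensuring the pre-saturation region is used).
#' @param n_max Cap on signal length used (default 4096; the neighbor search
#'   is quadratic).
#' @return Scalar exponent in nats/sample.
#' @export
largest_lyapunov <- function(x, m = 2, tau = NULL, horizon = 20,
                             fit_range = NULL, n_max = 4096) {
  if (stats::sd(x) == 0) stop("Lyapunov exponent undefined for a constant signal",
                              call. = FALSE)
  if (length(x) > n_max) x <- x[seq_len(n_max)]
  if (is.null(tau)) tau <- acf_delay(x)
  theiler <- mean_period(x)
  y <- lyap_divergence_cpp(as.numeric(x), m, tau, theiler, horizon)
  k <- 0:horizon
  ok <- is.finite(y)
  if (is.null(fit_range)) {
    span <- max(y[ok]) - y[ok][1]
    if (span <= 0) return(0)
    stop_k <- which(y - y[ok][1] >= 0.6 * span)[1] - 1L
    fit_range <- 1:max(2L, min(stop_k, horizon))
  }
  sel <- ok & k %in% fit_range
  unname(stats::coef(stats::lm(y[sel] ~ k[sel]))[2])
}

# Mean period in samples from the spectral centroid of the periodogram.
mean_period <- function(x) {
  n <- length(x)
  p <- abs(stats::fft(x - mean(x))[2:(n %/% 2)])^2
  f <- (1:(n %/% 2 - 1)) / n
  fm <- sum(f * p) / sum(p)
  max(1L, min(as.integer(round(1 / fm)), n %/% 10))
}

#' C0-complexity
#'
#' Fraction of signal power left after removing the "regular" spectral
#' components: Fourier coefficients whose squared magnitude strictly exceeds
#' the mean squared magnitude are kept as the regular part, everything else
#' is discarded, and C0 is the power ratio of the residual to the original.
#' Always in `[0, 1]`; near 0 for a pure tone, 1 for a flat spectrum.
#'
#' @param x Numeric signal with nonzero energy.
#' @return Scalar in `[0, 1]`.
#' @export
c0_complexity <- function(x) {
  if (sum(x^2) == 0) stop("C0-complexity undefined for an all-zero signal",
                          call. = FALSE)
  X <- stats::fft(x)
  M <- mean(Mod(X)^2)
  Y <- ifelse(Mod(X)^2 > M, X, 0 + 0i)
  y <- Re(stats::fft(Y, inverse = TRUE)) / length(x)
  sum((x - y)^2) / sum(x^2)
}

#' Correlation (K2) entropy
#'
#' Practical estimator of the Kolmogorov-Sinai entropy rate: the mean of
#' `ln[C_m(r) / C_{m+1}(r)] / tau` over the scaling region of the correlation
#' integrals. Zero for regular (periodic) dynamics, positive and finite for
#' chaos, in nats per sample.
#'
#' @param x Numeric signal.
#' @param m Base embedding dimension (default 2).
#' @param tau Embedding delay (default from the autocorrelation).
#' @param max_points Subsampling cap for the pair sums (default 2000).
#' @return Nonnegative scalar, nats/sample.
#' @export
kolmogorov_entropy <- function(x, m = 2, tau = NULL, max_points = 2000) {
  if (stats::sd(x) == 0) return(0)
  if (is.null(tau)) tau <- acf_delay(x)
  s <- stats::sd(x)
  rs <- s * exp(seq(log(0.01), log(2), length.out = 24))
  C <- corr_sums_cpp(as.numeric(x), tau, m + 1L, rs, tau, max_points)
  cm <- C[m, ]; cm1 <- C[m + 1L, ]
  ok <- which(cm1 > 0 & cm > 0 & cm < 0.5)
  if (length(ok) < 3) stop("no usable scaling region for K2", call. = FALSE)
  lr <- log(rs[ok]); mid <- mean(range(lr)); half <- diff(range(lr)) / 4
  keep <- ok[lr >= mid - half & lr <= mid + half]
  if (length(keep) < 2) keep <- ok
  max(0, mean(log(cm[keep] / cm1[keep])) / tau)
}

#' Shannon entropy of the amplitude distribution
#'
#' Entropy of the equal-width amplitude histogram over `[min(x), max(x)]`,
#' in nats; empty bins are skipped. Bounded by `ln(n_bins)`; a constant
#' signal has entropy 0.
#'
#' @param x Numeric signal.
#' @param n_bins Number of histogram bins (default 16).
#' @return Scalar in `[0, ln(n_bins)]`.
#' @export
shannon_entropy <- function(x, n_bins = 16) {
  stopifnot(n_bins >= 2)
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  idx <- pmin(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  p <- tabulate(idx, n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Approximate entropy
#'
#' Pincus regularity statistic `Phi^m(r) - Phi^(m+1)(r)` with Chebyshev
#' (maximum coordinate) distance and self-matches included. Higher values
#' indicate more irregular fluctuations.
#'
#' @param x Numeric signal.
#' @param m Pattern length (default 2).
#' @param r Tolerance in signal units; default `0.2 * sd(x)` (set
#'   `r_mode = "variance"` for a literal `0.2 * var(x)`).
#' @param r_mode `"sd"` (default) or `"variance"` scaling of the default
#'   tolerance.
#' @return Nonnegative scalar; 0 for a constant signal.
#' @export
approximate_entropy <- function(x, m = 2, r = NULL,
                                r_mode = c("sd", "variance")) {
  r_mode <- match.arg(r_mode)
  s <- stats::sd(x)
  if (s == 0) return(0)
  if (is.null(r)) r <- if (r_mode == "sd") 0.2 * s else 0.2 * s^2
  if (r <= 0) stop("`r` must be positive", call. = FALSE)
  apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Nonlinear feature vector of a segment
#'
#' The eight per-channel nonlinear descriptors - DFA exponent, Higuchi
#' fractal dimension, correlation dimension, largest Lyapunov exponent,
#' C0-complexity, K2 entropy, Shannon entropy, approximate entropy - for
#' each of the 19 canonical channels: 152 features named
#' `<descriptor>_<channel>`.
#'
#' @param seg An [eeg_recording] with the canonical channels.
#' @param lyap_m Embedding dimension for the Lyapunov estimator (default 5
#'   for flow-like EEG data).
#' @return Named numeric vector of length 152.
#' @export
nonlinear_features <- function(seg, lyap_m = 5) {
  stopifnot(inherits(seg, "eeg_recording"))
  require_canonical(seg)
  descs <- c("dfa", "hfd", "cd", "lle", "c0", "ke", "shannon", "apen")
  out <- numeric(0)
  for (d in descs) {
    v <- vapply(eeg_channels_1020, function(ch) {
      x <- seg$data[match(ch, seg$channels), ]
      tryCatch(switch(d,
        dfa = dfa(x),
        hfd = higuchi_fd(x),
        cd = correlation_dimension(x),
        lle = largest_lyapunov(x, m = lyap_m),
        c0 = c0_complexity(x),
        ke = kolmogorov_entropy(x),
        shannon = shannon_entropy(x),
        apen = approximate_entropy(x)
      ), error = function(e) {
        stop("descriptor '", d, "' failed on channel ", ch, ": ",
             conditionMessage(e), call. = FALSE)
      })
    }, 0)
    names(v) <- paste0(d, "_", eeg_channels_1020)
    out <- c(out, v)
  }
  out
}
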