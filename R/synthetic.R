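#' Specification of a synthetic EEG cohort
#'
#' Describes a two-group (MCI / HC) cohort of 19-channel synthetic
#' resting-state recordings: band-limited oscillations at delta/theta/alpha/
#' beta centre frequencies with per-group amplitudes, a shared lagged latent
#' source mixed into selected channel pairs with per-group coupling strength,
#' and 1/f^noise_exp background noise. Defaults emulate a small clinical
#' cohort (18 MCI / 16 HC, 256 Hz, five minutes) with the group contrasts
#' typically reported for MCI: attenuated alpha/beta rhythm and reduced
#' fronto-central connectivity.
#'
#' @param n_mci,n_hc Subject counts (defaults 18 and 16).
#' @param duration_s Recording length in seconds (default 300).
#' @param fs Sampling rate in Hz (default 256).
#' @param band_amp Named list with per-group named amplitude vectors (uV) for
#'   the delta/theta/alpha/beta oscillations.
#' @param coupling Named list of per-group source-mixing coefficients in
#'   `[0, 1]`.
#' @param coupled_pairs List of channel-label pairs that share the lagged
#'   latent source.
#' @param lag Lag of the shared source in the second channel of each pair,
#'   in samples (default 10, matching the SL embedding lag).
#' @param noise_exp Spectral exponent of the background noise (default 1).
#' @param noise_amp Background noise standard deviation in uV (default 5).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mci = 18, n_hc = 16, duration_s = 300, fs = 256,
                        band_amp = list(
                          HC = c(delta = 4, theta = 5, alpha = 10, beta = 5),
                          MCI = c(delta = 4, theta = 6, alpha = 7, beta = 4)
                        ),
                        coupling = list(HC = 0.6, MCI = 0.3),
                        coupled_pairs = list(c("F3", "C3"), c("Fp1", "F3"),
                                             c("P4", "Cz"), c("C3", "C4")),
                        lag = 10, noise_exp = 1, noise_amp = 5, seed = 1) {
  stopifnot(n_mci >= 1, n_hc >= 1, fs > 0, duration_s > 0,
            all(unlist(coupling) >= 0), all(unlist(coupling) <= 1))
  structure(list(n_mci = n_mci, n_hc = n_hc, duration_s = duration_s,
                 fs = fs, band_amp = band_amp, coupling = coupling,
                 coupled_pairs = coupled_pairs, lag = as.integer(lag),
                 noise_exp = noise_exp, noise_amp = noise_amp,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Band centre frequencies (Hz) for the synthetic oscillations: placed well
# inside each band so jittered tones cannot straddle a band edge.
synth_centres <- c(delta = 2, theta = 6, alpha = 10, beta = 20)

# Gaussian noise with a 1/f^exp amplitude-shaped spectrum, unit variance.
pink_noise <- function(n, exponent = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # avoid dividing by zero at DC
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  X <- X / f^(exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a synthetic EEG cohort
#'
#' Builds `n_mci + n_hc` labelled 19-channel recordings per the
#' [cohort_spec()]: per-channel sums of jittered band oscillations with
#' random phases, plus the shared lagged source in the coupled pairs, plus
#' independent 1/f background noise. Bit-identical for identical specs.
#'
#' @param spec A [cohort_spec()].
#' @return List of [eeg_recording] objects with labels.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_samp <- round(spec$duration_s * spec$fs)
  t <- (0:(n_samp - 1)) / spec$fs
  groups <- c(rep("MCI", spec$n_mci), rep("HC", spec$n_hc))
  lapply(seq_along(groups), function(si) {
    g <- groups[si]
    withr::with_seed(spec$seed * 1000L + si, {
      amps <- spec$band_amp[[g]]
      data <- matrix(0, length(eeg_channels_1020), n_samp)
      for (ch in seq_len(nrow(data))) {
        x <- numeric(n_samp)
        for (b in seq_along(synth_centres)) {
          # per-channel frequency jitter keeps uncoupled channels from
          # sharing a deterministic oscillation, so their baseline
          # synchronization stays at chance level
          f0 <- synth_centres[b] * (1 + stats::runif(1, -0.1, 0.1))
          phase <- stats::runif(1, 0, 2 * pi)
          x <- x + amps[[names(synth_centres)[b]]] *
            sin(2 * pi * f0 * t + phase)
        }
        x <- x + spec$noise_amp * pink_noise(n_samp, spec$noise_exp)
        data[ch, ] <- x
      }
      # shared latent source: convex mixing so coupling 1 makes the two
      # channels identical lagged copies of the source (maximal
      # synchronization) while coupling 0 leaves them independent
      c_mix <- spec$coupling[[g]]
      if (c_mix > 0) {
        for (pair in spec$coupled_pairs) {
          src <- pink_noise(n_samp + spec$lag, exponent = 0.5)
          a <- match(pair[1], eeg_channels_1020)
          b <- match(pair[2], eeg_channels_1020)
          sa <- stats::sd(data[a, ]); sb <- stats::sd(data[b, ])
          data[a, ] <- (1 - c_mix) * data[a, ] +
            c_mix * sa * src[(spec$lag + 1):(n_samp + spec$lag)]
          data[b, ] <- (1 - c_mix) * data[b, ] +
            c_mix * sb * src[1:n_samp]
        }
      }
      eeg_recording(data, fs = spec$fs,
                    subject_id = sprintf("%s%02d", g, si), label = g)
    })
  })
}

#' Generate known-answer test signals
#'
#' Deterministic single-channel signals with known theoretical properties,
#' used as oracles for the nonlinear descriptors: white / Brownian / 1/f
#' noise, sinusoids, the logistic and Henon maps, impulses and constants.
#'
#' @param kind One of `"white"`, `"brownian"`, `"pink"`, `"sine"`,
#'   `"logistic_map"`, `"henon_map"`, `"impulse"`, `"constant"`.
#' @param length Number of samples (>= 2).
#' @param seed Integer seed for the stochastic kinds.
#' @param sd Standard deviation for the noise kinds (default 1).
#' @param period Sine period in samples (default 100).
#' @param amplitude Sine amplitude (default 1).
#' @param r,x0 Logistic-map rate and start (defaults 4 and 0.3).
#' @param a,b Henon-map parameters (defaults 1.4 and 0.3).
#' @param value Constant value (default 1).
#' @param exponent 1/f exponent for `"pink"` (default 1).
#' @return Numeric vector of `length` samples.
#' @export
gen_known_signal <- function(kind, length, seed = 1, sd = 1, period = 100,
                             amplitude = 1, r = 4, x0 = 0.3, a = 1.4,
                             b = 0.3, value = 1, exponent = 1) {
  kind <- match.arg(kind, c("white", "brownian", "pink", "sine",
                            "logistic_map", "henon_map", "impulse",
                            "constant"))
  stopifnot(length >= 2)
  n <- length
  switch(kind,
    white = withr::with_seed(seed, stats::rnorm(n, sd = sd)),
    brownian = withr::with_seed(seed, cumsum(stats::rnorm(n, sd = sd))),
    pink = withr::with_seed(seed, sd * pink_noise(n, exponent)),
    sine = amplitude * sin(2 * pi * (0:(n - 1)) / period),
    logistic_map = {
      if (x0 <= 0 || x0 >= 1) stop("logistic map needs x0 in (0, 1)",
                                   call. = FALSE)
      x <- numeric(n); x[1] <- x0
      for (i in 2:n) x[i] <- r * x[i - 1] * (1 - x[i - 1])
      x
    },
    henon_map = {
      burn <- 100
      x <- 0.1; y <- 0.1
      out <- numeric(n)
      for (i in seq_len(n + burn)) {
        xn <- 1 - a * x^2 + y
        y <- b * x
        x <- xn
        if (!is.finite(x)) stop("Henon orbit diverged", call. = FALSE)
        if (i > burn) out[i - burn] <- x
      }
      out
    },
    impulse = c(1, rep(0, n - 1)),
    constant = rep(value, n)
  )
}

#' Write a cohort to a fixture directory
#'
#' One signal file per recording (CSV by default, optionally EDF) plus a
#' `manifest.csv` listing subject id, label, sampling rate, duration and
#' file name.
#'
#' @param recordings List of [eeg_recording] objects.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"edf"`.
#' @return Path of the manifest, invisibly.
#' @export
write_fixtures <- function(recordings, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(recordings, function(rec) {
    fname <- paste0(rec$subject_id, ".", format)
    write_eeg(rec, file.path(dir, fname))
    tibble::tibble(subject_id = rec$subject_id, label = rec$label,
                   fs = rec$fs, duration_s = ncol(rec$data) / rec$fs,
                   file = fname)
  })
  manifest <- dplyr::bind_rows(rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a fixture directory back into recordings
#'
#' @param dir Directory containing a `manifest.csv` written by
#'   [write_fixtures()].
#' @return List of [eeg_recording] objects.
#' @export
read_fixtures <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(manifest)), function(i) {
    read_eeg(file.path(dir, manifest$file[i]), fs = manifest$fs[i],
             subject_id = manifest$subject_id[i], label = manifest$label[i])
  })
}
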