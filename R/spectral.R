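#' Default frequency band definitions
#'
#' Delta, theta, alpha and beta bands as half-open intervals `[lo, hi)` in Hz.
#' Theta/alpha/beta follow the conventional 4-8 / 8-13 / 13-32 Hz edges; the
#' delta band starts at the 0.5 Hz high-pass edge of the standard
#' preprocessing filter.
#'
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    lo = c(0.5, 4, 8, 13),
    hi = c(4, 8, 13, 32)
  )
}

# Homologous right/left channel pairs used for interhemispheric asymmetry.
ia_pairs <- function() {
  tibble::tibble(
    right = c("Fp2", "F4", "F8", "C4", "T4", "P4", "T6", "O2"),
    left  = c("Fp1", "F3", "F7", "C3", "T3", "P3", "T5", "O1")
  )
}

#' Welch power spectral density estimate
#'
#' Averages modified periodograms of Hamming-tapered, overlapping segments.
#' The one-sided density is normalised so that its integral over frequency
#' approximates the signal variance (units^2 / Hz).
#'
#' @param x Single-channel numeric signal.
#' @param fs Sampling rate (Hz).
#' @param win_len Segment length in samples (default 512, i.e. 2 s at 256 Hz).
#' @param overlap_frac Fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @return List of class `psd_estimate` with `freqs` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, win_len = 512, overlap_frac = 0.5) {
  n <- length(x)
  if (win_len > n) stop("`win_len` exceeds signal length", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must be in [0, 1)", call. = FALSE)
  }
  step <- max(1L, as.integer(round(win_len * (1 - overlap_frac))))
  starts <- seq(1L, n - win_len + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(win_len - 1)) / (win_len - 1))
  u <- sum(w^2)                      # window power normalisation
  n_freq <- win_len %/% 2 + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + win_len - 1L)] * w
    p <- abs(stats::fft(seg))[1:n_freq]^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist when present)
    p[2:(n_freq - 1L)] <- 2 * p[2:(n_freq - 1L)]
    if (win_len %% 2 == 1L) p[n_freq] <- 2 * p[n_freq]
    acc <- acc + p
  }
  structure(
    list(freqs = (0:(n_freq - 1L)) * fs / win_len, psd = acc / length(starts)),
    class = "psd_estimate"
  )
}

#' Band power from a PSD estimate
#'
#' Trapezoidal integral of the power spectral density over the half-open
#' interval `[lo, hi)`.
#'
#' @param psd A `psd_estimate` from [welch_psd()].
#' @param lo,hi Band edges in Hz.
#' @return Nonnegative scalar power (signal units squared).
#' @export
band_power <- function(psd, lo, hi) {
  f <- psd$freqs
  if (lo < f[1] || hi > f[length(f)] + diff(f)[1]) {
    stop("band [", lo, ", ", hi, ") outside PSD frequency grid", call. = FALSE)
  }
  keep <- f >= lo & f < hi
  if (sum(keep) < 2L) return(0)
  sum(diff(f[keep]) * (utils::head(psd$psd[keep], -1) +
                         utils::tail(psd$psd[keep], -1)) / 2)
}

#' Interhemispheric asymmetry
#'
#' Natural-log band-power ratio between a right-hemisphere channel and its
#' left homolog: `IA = ln(P_right) - ln(P_left)`. Positive values mean more
#' power on the right.
#'
#' @param p_right,p_left Strictly positive band powers.
#' @return Dimensionless asymmetry index.
#' @export
interhemispheric_asymmetry <- function(p_right, p_left) {
  if (any(p_right <= 0) || any(p_left <= 0)) {
    stop("band powers must be positive for the log-ratio", call. = FALSE)
  }
  log(p_right) - log(p_left)
}

#' Spectral feature vector of a segment
#'
#' For a canonical 19-channel segment: band power in each of the four bands
#' for every channel (76 features, `bp_<band>_<channel>`) plus the
#' interhemispheric asymmetry of each band for the eight homologous pairs
#' (32 features, `ia_<band>_<right>-<left>`) - 108 features in total.
#'
#' @param seg An [eeg_recording] with the 19 canonical channels.
#' @param bands Band definition tibble as from [eeg_bands()].
#' @param win_len,overlap_frac Welch parameters, see [welch_psd()].
#' @return Named numeric vector of length 108.
#' @export
spectral_features <- function(seg, bands = eeg_bands(),
                              win_len = NULL, overlap_frac = 0.5) {
  stopifnot(inherits(seg, "eeg_recording"))
  require_canonical(seg)
  if (is.null(win_len)) win_len <- min(512L, ncol(seg$data))
  psds <- lapply(seq_len(nrow(seg$data)),
                 function(i) welch_psd(seg$data[i, ], seg$fs, win_len,
                                       overlap_frac))
  names(psds) <- seg$channels

  bp <- matrix(NA_real_, nrow(bands), length(seg$channels),
               dimnames = list(bands$band, seg$channels))
  for (b in seq_len(nrow(bands))) {
    for (ch in seg$channels) {
      bp[b, ch] <- band_power(psds[[ch]], bands$lo[b], bands$hi[b])
    }
  }
  out <- numeric(0)
  for (b in bands$band) {
    v <- bp[b, eeg_channels_1020]
    names(v) <- paste0("bp_", b, "_", eeg_channels_1020)
    out <- c(out, v)
  }
  prs <- ia_pairs()
  for (b in bands$band) {
    v <- interhemispheric_asymmetry(bp[b, prs$right], bp[b, prs$left])
    names(v) <- paste0("ia_", b, "_", prs$right, "-", prs$left)
    out <- c(out, v)
  }
  out
}

require_canonical <- function(seg) {
  missing <- setdiff(eeg_channels_1020, seg$channels)
  if (length(missing)) {
    stop("segment is missing canonical channels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
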