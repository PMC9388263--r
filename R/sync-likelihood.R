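#' Synchronization-likelihood parameters
#'
#' Parameter block for the synchronization-likelihood (SL) estimator:
#' reference recurrence probability `p_ref`, embedding lag `l` and dimension
#' `m`, and the Theiler (`w1`) / sharpening (`w2`) window half-widths in
#' samples. Recurrences are counted only over `w1 < |i - j| < w2`, which
#' suppresses autocorrelation artifacts while keeping the estimate local in
#' time. Defaults are the values used for 256 Hz resting-state EEG.
#'
#' @param p_ref Reference probability, `0 < p_ref << 1` (default 0.01).
#' @param l Embedding lag in samples (default 10).
#' @param m Embedding dimension (default 10).
#' @param w1,w2 Window half-widths in samples, `0 < w1 < w2`
#'   (defaults 100 and 410).
#' @return List of class `sl_params`.
#' @export
sl_params <- function(p_ref = 0.01, l = 10, m = 10, w1 = 100, w2 = 410) {
  stopifnot(p_ref > 0, p_ref < 1, l >= 1, m >= 1, w1 > 0, w2 > w1)
  structure(list(p_ref = p_ref, l = as.integer(l), m = as.integer(m),
                 w1 = as.integer(w1), w2 = as.integer(w2)),
            class = "sl_params")
}

#' Time-delay embedding
#'
#' Reconstructs state vectors `(x_i, x_{i+l}, ..., x_{i+(m-1)l})` from a
#' scalar signal.
#'
#' @param x Numeric signal of length N.
#' @param m Embedding dimension.
#' @param l Lag in samples.
#' @return Matrix with `N - (m-1)*l` rows (state vectors) and `m` columns.
#' @export
embed_delay <- function(x, m, l) {
  n <- length(x) - (m - 1) * l
  if (n < 1) stop("signal too short for embedding", call. = FALSE)
  sapply(seq_len(m), function(k) x[(1:n) + (k - 1) * l], simplify = "array")
}

#' Critical recurrence distance at a reference probability
#'
#' The smallest distance `eps` such that at least a fraction `p_ref` of the
#' state vectors in the window `w1 < |i - j| < w2` lie within `eps` of vector
#' `i`; computed as the distance to the `ceil(p_ref * W)`-th nearest valid
#' neighbor (W = number of valid indices).
#'
#' @param vectors State-vector matrix as from [embed_delay()].
#' @param i Reference row index (1-based).
#' @param p_ref Reference probability.
#' @param w1,w2 Window half-widths in samples.
#' @return Scalar distance.
#' @export
critical_distance <- function(vectors, i, p_ref, w1, w2) {
  n <- nrow(vectors)
  j <- seq_len(n)
  valid <- abs(j - i) > w1 & abs(j - i) < w2
  if (!any(valid)) stop("no valid neighbors in the window", call. = FALSE)
  d <- sqrt(colSums((t(vectors[valid, , drop = FALSE]) - vectors[i, ])^2))
  k <- max(1L, ceiling(p_ref * length(d)))
  sort(d, partial = k)[k]
}

#' Synchronization likelihood between two signals
#'
#' Estimates generalized synchronization between two simultaneously recorded
#' signals from coincidences of state-space recurrences. For each reference
#' time the per-channel critical distance is fixed so that a fraction
#' `p_ref` of windowed neighbors recur; the likelihood is the fraction of one
#' channel's recurrences at which the other channel recurs too, averaged over
#' reference times and both channels. Identical signals give exactly 1;
#' independent signals give approximately `p_ref`.
#'
#' @param x,y Equal-length numeric signals.
#' @param params An [sl_params()] block.
#' @param stride Reference-time subsampling step (default 1 = every vector;
#'   larger values trade variance for speed).
#' @return Scalar in `[0, 1]`.
#' @export
sync_likelihood_pair <- function(x, y, params = sl_params(), stride = 1L) {
  stopifnot(inherits(params, "sl_params"), length(x) == length(y))
  need <- (params$m - 1) * params$l + params$w1 + 2
  if (length(x) < need) {
    stop("signals too short for embedding plus Theiler window (need >= ",
         need, " samples)", call. = FALSE)
  }
  sl_pair_cpp(as.numeric(x), as.numeric(y), params$m, params$l,
              params$p_ref, params$w1, params$w2, as.integer(stride))
}

#' Pairwise synchronization-likelihood matrix of a segment
#'
#' Computes the SL for every unordered pair of the 19 canonical channels
#' (171 pairs); the diagonal is not computed.
#'
#' @param seg An [eeg_recording] with the canonical channels.
#' @param params An [sl_params()] block.
#' @param stride Reference-time subsampling step, see [sync_likelihood_pair()].
#' @return Object of class `sl_matrix`: list with the symmetric `values`
#'   matrix (diagonal `NA`) and `channels`.
#' @export
sl_matrix <- function(seg, params = sl_params(), stride = 1L) {
  stopifnot(inherits(seg, "eeg_recording"))
  require_canonical(seg)
  chs <- eeg_channels_1020
  k <- length(chs)
  vals <- matrix(NA_real_, k, k, dimnames = list(chs, chs))
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      s <- sync_likelihood_pair(seg$data[match(chs[a], seg$channels), ],
                                seg$data[match(chs[b], seg$channels), ],
                                params, stride)
      vals[a, b] <- vals[b, a] <- s
    }
  }
  structure(list(values = vals, channels = chs), class = "sl_matrix")
}

#' Connectivity feature vector of a segment
#'
#' Flattens the upper triangle of [sl_matrix()] into the 171 named features
#' `sl_<chA>-<chB>` (A before B in canonical order).
#'
#' @inheritParams sl_matrix
#' @return Named numeric vector of length 171.
#' @export
connectivity_features <- function(seg, params = sl_params(), stride = 1L) {
  m <- sl_matrix(seg, params, stride)
  sl_features_from_matrix(m)
}

sl_features_from_matrix <- function(m) {
  chs <- m$channels
  k <- length(chs)
  out <- numeric(k * (k - 1) / 2)
  nm <- character(length(out))
  idx <- 1L
  for (a in 1:(k - 1)) {
    for (b in (a + 1):k) {
      out[idx] <- m$values[a, b]
      nm[idx] <- paste0("sl_", chs[a], "-", chs[b])
      idx <- idx + 1L
    }
  }
  names(out) <- nm
  out
}

#' Export an SL matrix as a data frame
#'
#' @param x An `sl_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `sl` (upper triangle).
#' @export
tidy.sl_matrix <- function(x, ...) {
  v <- sl_features_from_matrix(x)
  parts <- strsplit(sub("^sl_", "", names(v)), "-", fixed = TRUE)
  tibble::tibble(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    sl = unname(v)
  )
}

#' Heatmap of a synchronization-likelihood matrix
#'
#' @param object An `sl_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sl_matrix <- function(object, ...) {
  df <- tidy(object)
  df$from <- factor(df$from, levels = object$channels)
  df$to <- factor(df$to, levels = object$channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$sl)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "SL") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
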