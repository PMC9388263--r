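#' Canonical 10-20 channel order
#'
#' The 19 scalp electrodes of the international 10-20 system, in the fixed
#' order used throughout the package. Odd indices are left-hemisphere sites,
#' even are right, z is midline.
#'
#' @format Character vector of length 19.
#' @export
eeg_channels_1020 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
  "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

#' Construct an EEG recording
#'
#' Container for a multichannel EEG signal: a channels x samples matrix of
#' amplitudes (microvolts) plus sampling rate, channel labels, subject id and
#' diagnostic label.
#'
#' @param data Numeric matrix, rows = channels, columns = time samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Character vector of unique channel labels, one per row.
#' @param subject_id Opaque subject identifier.
#' @param label Diagnostic class: `"MCI"`, `"HC"` or `"UNKNOWN"`.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(19 * 256), 19), fs = 256)
#' rec
#' @export
eeg_recording <- function(data, fs, channels = eeg_channels_1020,
                          subject_id = "S1", label = "UNKNOWN") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("EEG samples must all be finite", call. = FALSE)
  }
  channels <- as.character(channels)
  if (anyDuplicated(channels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (length(channels) != nrow(data)) {
    stop("number of channel labels (", length(channels),
         ") does not match number of rows (", nrow(data), ")", call. = FALSE)
  }
  label <- match.arg(label, c("MCI", "HC", "UNKNOWN"))
  structure(
    list(data = data, fs = fs, channels = channels,
         subject_id = as.character(subject_id), label = label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)  subject=%s  label=%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$subject_id, x$label
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# Reorder rows to canonical 10-20 order when all 19 canonical labels are present.
canonicalise_channels <- function(rec) {
  if (all(eeg_channels_1020 %in% rec$channels) &&
      length(rec$channels) == length(eeg_channels_1020)) {
    idx <- match(eeg_channels_1020, rec$channels)
    rec$data <- rec$data[idx, , drop = FALSE]
    rec$channels <- eeg_channels_1020
  }
  rec
}

#' Read an EEG recording from disk
#'
#' Reads a multichannel recording from a CSV matrix (header row of channel
#' labels, one column per channel, one row per sample) or from a 16-bit EDF
#' file. When all 19 canonical 10-20 labels are present, channels are
#' reordered to the canonical order.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"edf"`. Default guesses from the extension.
#' @param fs Sampling rate in Hz; required for CSV (EDF carries its own).
#' @param subject_id,label Metadata attached to the recording; default
#'   subject id is the file stem.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path, format = c("auto", "csv", "edf"), fs = NULL,
                     subject_id = NULL, label = "UNKNOWN") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  }
  if (format == "csv") {
    if (is.null(fs)) stop("`fs` is required when reading CSV", call. = FALSE)
    df <- utils::read.csv(path, check.names = FALSE)
    if (!all(vapply(df, is.numeric, logical(1)))) {
      stop("non-numeric values in CSV signal matrix: ", path, call. = FALSE)
    }
    rec <- eeg_recording(t(as.matrix(df)), fs = fs, channels = names(df),
                         subject_id = subject_id, label = label)
  } else {
    hdr <- read_edf_impl(path)
    rec <- eeg_recording(hdr$data, fs = hdr$fs, channels = hdr$channels,
                         subject_id = subject_id, label = label)
  }
  canonicalise_channels(rec)
}

#' Write an EEG recording to disk
#'
#' @param rec An [eeg_recording].
#' @param path Output path; `.edf` extension selects EDF, otherwise CSV
#'   (header of channel labels, one column per channel).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf_impl(rec, path)
  } else {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channels
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero phase, no group delay) to every channel. Defaults follow the common
#' resting-state EEG band of interest, 0.5-32 Hz.
#'
#' @param rec An [eeg_recording].
#' @param lo,hi Band edges in Hz; `0 < lo < hi < fs/2`.
#' @param order Butterworth order of the one-pass prototype (default 4).
#' @return A filtered [eeg_recording] of the same shape.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 32, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq) stop("`hi` must be below the Nyquist frequency ", nyq, " Hz",
                      call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  # filtfilt needs some run-in; 3x the filter length is a safe floor
  if (ncol(rec$data) <= 3 * (length(bf$a) + length(bf$b))) {
    stop("recording too short for zero-phase filtering", call. = FALSE)
  }
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rec
}

#' Slice a recording into fixed-length non-overlapping segments
#'
#' Cuts the recording into contiguous windows of `window_s` seconds; a
#' trailing partial window is discarded. Each segment inherits the parent's
#' sampling rate, channels, subject id and label.
#'
#' @param rec An [eeg_recording].
#' @param window_s Window length in seconds (default 60).
#' @return List of [eeg_recording] segments (possibly empty, with a warning,
#'   when the recording is shorter than one window).
#' @export
segment <- function(rec, window_s = 60) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0)
  n_win <- round(window_s * rec$fs)
  n <- ncol(rec$data)
  k <- n %/% n_win
  if (k == 0L) {
    warning("recording shorter than one window; returning no segments",
            call. = FALSE)
    return(list())
  }
  lapply(seq_len(k), function(i) {
    seg <- rec
    seg$data <- rec$data[, ((i - 1L) * n_win + 1L):(i * n_win), drop = FALSE]
    seg
  })
}
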