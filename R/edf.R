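# Minimal EDF (European Data Format) support: standard 16-bit continuous
# recordings, one data-record duration, identical sampling rate per signal.
# Amplitudes are mapped between physical and digital ranges per the header.

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  sprintf(paste0("%-", n, "s"), x)
}

read_edf_impl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  read_str(8)                       # version
  read_str(80); read_str(80)        # patient, recording id
  read_str(8); read_str(8)          # start date, time
  header_bytes <- as.integer(read_str(8))
  read_str(44)                      # reserved
  n_rec <- as.integer(read_str(8))
  rec_dur <- as.numeric(read_str(8))
  ns <- as.integer(read_str(4))
  labels <- vapply(seq_len(ns), function(i) read_str(16), character(1))
  for (i in seq_len(ns)) read_str(80)   # transducer
  for (i in seq_len(ns)) read_str(8)    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_str(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_str(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(read_str(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(read_str(8)), 0)
  for (i in seq_len(ns)) read_str(80)   # prefiltering
  n_samp <- vapply(seq_len(ns), function(i) as.integer(read_str(8)), 0L)
  for (i in seq_len(ns)) read_str(32)   # reserved
  seek(con, header_bytes)
  if (length(unique(n_samp)) != 1L) {
    stop("mixed per-signal sampling rates in EDF are not supported",
         call. = FALSE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_rec * n_samp[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = n_samp[s], size = 2,
                     signed = TRUE, endian = "little")
      cols <- ((r - 1L) * n_samp[s] + 1L):(r * n_samp[s])
      data[s, cols] <- phys_min[s] + gain[s] * (dig - dig_min[s])
    }
  }
  list(data = data, fs = n_samp[1] / rec_dur, channels = labels)
}

write_edf_impl <- function(rec, path, record_s = 1) {
  ns <- nrow(rec$data)
  n_samp <- as.integer(round(record_s * rec$fs))
  n_rec <- ncol(rec$data) %/% n_samp
  if (n_rec < 1L) stop("recording shorter than one EDF data record",
                       call. = FALSE)
  used <- rec$data[, seq_len(n_rec * n_samp), drop = FALSE]
  phys_min <- apply(used, 1, min)
  phys_max <- apply(used, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, n) writeBin(charToRaw(edf_pad(x, n)), con)
  w("0", 8)
  w(rec$subject_id, 80); w("eegmci export", 80)
  w("01.01.00", 8); w("00.00.00", 8)
  w(256 * (1 + ns), 8); w("EDF", 44)
  w(n_rec, 8); w(format(record_s), 8); w(ns, 4)
  for (ch in rec$channels) w(ch, 16)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w("uV", 8)
  for (i in seq_len(ns)) w(format(signif(phys_min[i], 7)), 8)
  for (i in seq_len(ns)) w(format(signif(phys_max[i], 7)), 8)
  for (i in seq_len(ns)) w(dig_min, 8)
  for (i in seq_len(ns)) w(dig_max, 8)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(n_samp, 8)
  for (i in seq_len(ns)) w("", 32)
  pmin7 <- as.numeric(format(signif(phys_min, 7)))
  pmax7 <- as.numeric(format(signif(phys_max, 7)))
  gain <- (pmax7 - pmin7) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      cols <- ((r - 1L) * n_samp + 1L):(r * n_samp)
      dig <- round((used[s, cols] - pmin7[s]) / gain[s] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
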