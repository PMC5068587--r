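# Minimal EDF (European Data Format) I/O: standard 256-byte ASCII header plus
# per-signal headers, 16-bit little-endian samples, 1 s data records.  Covers
# what this pipeline needs (equal sampling rates, uV units); not a general
# EDF+ implementation.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a continuous EEG record as EDF
#'
#' Physical units are uV; each channel is scaled to the 16-bit digital range
#' against its own symmetric physical range.  The record is zero-padded to a
#' whole number of 1 s data records.  Missing values are stored as 0 (EDF has
#' no NA); export before artifact rejection, or alongside the rejection-mask
#' TSV, to preserve them.
#'
#' @param eeg a `continuous_eeg`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(eeg, path) {
  sig <- eeg$signal
  sig[is.na(sig)] <- 0
  fs <- eeg$fs
  ns <- ncol(sig)
  n_rec <- ceiling(nrow(sig) / fs)
  if (nrow(sig) < n_rec * fs)
    sig <- rbind(sig, matrix(0, n_rec * fs - nrow(sig), ns))
  phys_max <- pmax(apply(abs(sig), 2, max), 1)
  phys_max <- ceiling(phys_max)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(eeg$channels, 16),
    list(rep("", ns), 80),
    list(rep("uV", ns), 8),
    list(-phys_max, 8),
    list(phys_max, 8),
    list(rep(-32768, ns), 8),
    list(rep(32767, ns), 8),
    list(rep("", ns), 80),
    list(rep(fs, ns), 8),
    list(rep("", ns), 32))
  for (f in fields)
    writeChar(paste0(vapply(f[[1]], pad_field, "", width = f[[2]]),
                     collapse = ""), con, eos = NULL)
  # digital conversion per channel
  dig <- vapply(seq_len(ns), function(ch)
    as.integer(round(sig[, ch] / phys_max[ch] * 32767)), integer(nrow(sig)))
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    # channel-major within each record: all samples of channel 1, then 2, ...
    writeBin(as.integer(dig[idx, , drop = FALSE]), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_eeg_edf()]
#'
#' @param path EDF file path.
#' @return list with `signal` (samples x channels, physical units), `fs`,
#'   `channels`.
#' @export
read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)            # units
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / rec_dur
  sig <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = sum(spr), size = 2,
                   endian = "little", signed = TRUE)
    for (ch in seq_len(ns)) {
      v <- raw[(ch - 1) * spr[1] + seq_len(spr[1])]
      sig[(r - 1) * spr[1] + seq_len(spr[1]), ch] <-
        phys_min[ch] + (v - dig_min[ch]) * scale[ch]
    }
  }
  list(signal = sig, fs = fs, channels = labels)
}

#' Write / read the trial event table as a BIDS-style events TSV
#'
#' Columns: `onset` (arrow onset, s), `duration`, `trial_type`, `ssd`
#' (realised, s), `staircase`, `outcome`, `block`, `index`.
#'
#' @param events event table from a `continuous_eeg`.
#' @param path TSV path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset = events$onset_s, duration = 0,
                    trial_type = events$trial_type,
                    ssd = events$ssd_ms / 1000,
                    staircase = events$staircase,
                    outcome = events$outcome,
                    block = events$block, index = events$index)
  out$ssd[is.na(out$ssd)] <- NA
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
  data.frame(index = ev$index, block = ev$block, onset_s = ev$onset,
             stop_onset_s = ev$onset + ev$ssd,
             ssd_ms = ev$ssd * 1000,
             trial_type = ev$trial_type, staircase = ev$staircase,
             outcome = ev$outcome, stringsAsFactors = FALSE)
}
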