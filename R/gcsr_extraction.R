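# GCSR extraction: 1 s Hanning-windowed epochs around each stop signal (and a
# matched window in the adjacent Go trial), FFT log power at 4-12 Hz in 1 Hz
# bins, per-cell averaging, and the Stop-Go x SSD-quadratic conflict contrast.

GCSR_FREQS <- 4:12

#' Locate analysis epochs around stop signals
#'
#' One stop epoch per stop trial: a 1 s window starting 0.25 s before the
#' stop signal.  One matched Go epoch per stop trial, taken from the nearest
#' preceding Go trial in the same block (nearest following if none precede),
#' with the window placed at that Go trial's arrow onset plus the stop
#' trial's SSD minus 0.25 s — i.e. where the stop signal fell in the adjacent
#' stop trial.  Epochs extending past the record bounds are dropped, and a
#' stop trial without an eligible matched Go trial is excluded.
#'
#' @param eeg a `continuous_eeg` (provides the event table and record length).
#' @return data.frame of epochs: `trial_index`, `block`, `trial_type`
#'   ("stop"/"matched_go"), `ssd_level` (the stop trial's staircase),
#'   `start_s`, `start_sample` (1-based), `n_samples` (= fs).
#' @export
locate_epochs <- function(eeg) {
  ev <- eeg$events
  fs <- eeg$fs
  nrec <- nrow(eeg$signal)
  stops <- ev[ev$trial_type == "stop" & !is.na(ev$stop_onset_s), ]
  gos <- ev[ev$trial_type == "go", ]
  out <- list()
  for (i in seq_len(nrow(stops))) {
    st <- stops[i, ]
    cand <- gos[gos$block == st$block & gos$index < st$index, ]
    go <- if (nrow(cand) > 0) cand[which.max(cand$index), ] else {
      cand <- gos[gos$block == st$block & gos$index > st$index, ]
      if (nrow(cand) > 0) cand[which.min(cand$index), ] else NULL
    }
    if (is.null(go)) next
    starts <- c(stop = st$stop_onset_s - 0.25,
                matched_go = go$onset_s + st$ssd_ms / 1000 - 0.25)
    for (k in seq_along(starts)) {
      s0 <- round(starts[k] * fs) + 1
      if (s0 < 1 || s0 + fs - 1 > nrec) next
      out[[length(out) + 1L]] <- data.frame(
        trial_index = st$index, block = st$block,
        trial_type = names(starts)[k], ssd_level = st$staircase,
        start_s = starts[[k]], start_sample = s0, n_samples = fs,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(trial_index = integer(0), block = integer(0),
                      trial_type = character(0), ssd_level = character(0),
                      start_s = numeric(0), start_sample = integer(0),
                      n_samples = integer(0)))
  do.call(rbind, out)
}

hann_taper <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

#' Hanning-windowed log power at 4-12 Hz
#'
#' The 1 s epoch (128 samples at 128 Hz) is multiplied by a Hanning taper and
#' Fourier transformed; one-sided power `2 |X(f)|^2 / N^2` is taken at the
#' 1 Hz bins 4..12 and natural-log transformed with a small floor to avoid
#' -Inf on silent epochs.  An epoch containing any missing sample is
#' disqualified (all-NA return), signalling upstream exclusion.
#'
#' @param epoch numeric vector of exactly `fs` samples.
#' @param fs sampling rate (bin width is `fs / length(epoch)` = 1 Hz).
#' @param floor_eps power floor before the log (default 1e-12).
#' @return named numeric vector of 9 log-power values at 4..12 Hz.
#' @export
hann_log_power <- function(epoch, fs = FS_HZ, floor_eps = 1e-12) {
  if (length(epoch) != fs)
    stop_config("epoch must have exactly %d samples", fs)
  out_names <- paste0(GCSR_FREQS, "Hz")
  if (anyNA(epoch))
    return(setNames(rep(NA_real_, length(GCSR_FREQS)), out_names))
  X <- fft(hann_taper(fs) * epoch)
  p <- 2 * Mod(X[GCSR_FREQS + 1])^2 / fs^2
  setNames(log(pmax(p, floor_eps)), out_names)
}

# Matrix form (epochs in columns) used by the vectorised null-cohort
# simulator; proven equal to the scalar path in the test suite.
hann_log_power_matrix <- function(epochs, fs = FS_HZ, floor_eps = 1e-12) {
  stopifnot(nrow(epochs) == fs)
  X <- stats::mvfft(hann_taper(fs) * epochs)
  p <- 2 * Mod(X[GCSR_FREQS + 1, , drop = FALSE])^2 / fs^2
  out <- log(pmax(p, floor_eps))
  rownames(out) <- paste0(GCSR_FREQS, "Hz")
  out
}

#' Per-epoch log-power table
#'
#' Computes [hann_log_power()] for every epoch and analysis channel, in long
#' format.  Epochs overlapping masked (NA) samples yield NA log power and are
#' ignored by [average_cells()].
#'
#' @param eeg a (cleaned) `continuous_eeg`.
#' @param epochs epoch table from [locate_epochs()].
#' @param channels channels to analyse (default the frontal row F7..F8).
#' @return long data.frame: epoch keys + `channel`, `freq_hz`, `log_power`.
#' @export
epoch_power_table <- function(eeg, epochs,
                              channels = c("F7", "F3", "Fz", "F4", "F8")) {
  channels <- intersect(channels, eeg$channels)
  res <- lapply(seq_len(nrow(epochs)), function(i) {
    idx <- epochs$start_sample[i] + seq_len(epochs$n_samples[i]) - 1L
    per_ch <- lapply(channels, function(ch)
      data.frame(channel = ch, freq_hz = GCSR_FREQS,
                 log_power = unname(hann_log_power(eeg$signal[idx, ch], eeg$fs)),
                 stringsAsFactors = FALSE))
    cbind(epochs[rep(i, length(channels) * length(GCSR_FREQS)),
                 c("trial_index", "block", "trial_type", "ssd_level")],
          do.call(rbind, per_ch), row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$trial_type <- ifelse(out$trial_type == "stop", "stop", "go")
  out
}

#' Average log power into analysis cells
#'
#' Arithmetic mean of per-epoch log power within each cell
#' (block x channel x trial type x SSD level x frequency), ignoring rejected
#' (NA) epochs.  Empty cells appear explicitly with NA mean and
#' `n_trials = 0`.
#'
#' @param power_long long table from [epoch_power_table()].
#' @return data.frame: `block`, `channel`, `trial_type`, `ssd_level`,
#'   `freq_hz`, `mean_log_power`, `n_trials`.
#' @export
average_cells <- function(power_long) {
  grid <- expand.grid(block = sort(unique(power_long$block)),
                      channel = unique(power_long$channel),
                      trial_type = c("stop", "go"),
                      ssd_level = c("short", "medium", "long"),
                      freq_hz = GCSR_FREQS,
                      stringsAsFactors = FALSE)
  ok <- power_long[!is.na(power_long$log_power), ]
  keys <- c("block", "channel", "trial_type", "ssd_level", "freq_hz")
  if (nrow(ok) > 0) {
    m <- aggregate(ok["log_power"], ok[keys], mean)
    names(m)[names(m) == "log_power"] <- "mean_log_power"
    n <- aggregate(list(n_trials = ok$log_power), ok[keys], length)
    cells <- merge(merge(grid, m, by = keys, all.x = TRUE),
                   n, by = keys, all.x = TRUE)
  } else {
    cells <- grid
    cells$mean_log_power <- NA_real_
    cells$n_trials <- 0L
  }
  cells$n_trials[is.na(cells$n_trials)] <- 0L
  cells[order(cells$block, cells$channel, cells$trial_type,
              cells$ssd_level, cells$freq_hz), ]
}

#' Goal-conflict-specific rhythmicity spectrum
#'
#' For each (block, channel, frequency) — and participant, if present — the
#' Stop-Go log-power difference is formed at each SSD level, and GCSR is the
#' difference at the medium level minus the average of the short and long
#' levels (quadratic contrast with weights -1/2, 1, -1/2; positive values =
#' conflict-specific power excess).  Defined only where all six contributing
#' cells exist.
#'
#' @param cells cell table from [average_cells()], optionally with a
#'   `participant` column.
#' @return data.frame with the grouping keys, the six cell values
#'   (`<type>_<level>` columns) and `gcsr`.
#' @export
gcsr_spectrum <- function(cells) {
  keys <- intersect(c("participant", "block", "channel", "freq_hz"),
                    names(cells))
  pick <- function(tt, lev) {
    d <- cells[cells$trial_type == tt & cells$ssd_level == lev,
               c(keys, "mean_log_power")]
    names(d)[names(d) == "mean_log_power"] <- paste(tt, lev, sep = "_")
    d
  }
  combos <- expand.grid(tt = c("stop", "go"),
                        lev = c("short", "medium", "long"),
                        stringsAsFactors = FALSE)
  w <- Reduce(function(a, b) merge(a, b, by = keys, all = TRUE),
              lapply(seq_len(nrow(combos)),
                     function(i) pick(combos$tt[i], combos$lev[i])))
  d_short <- w$stop_short - w$go_short
  d_medium <- w$stop_medium - w$go_medium
  d_long <- w$stop_long - w$go_long
  w$gcsr <- d_medium - (d_short + d_long) / 2
  w[order(w[[keys[1]]]), ]
}

#' Extract a participant's GCSR spectrum from raw EEG
#'
#' Convenience wrapper: preprocess, locate epochs, compute spectra, average
#' cells, contrast.
#'
#' @param eeg a raw `continuous_eeg`.
#' @param channels analysis channels.
#' @param preprocess whether to run [preprocess_eeg()] first.
#' @return list with `cells` and `gcsr` tables.
#' @export
extract_gcsr <- function(eeg, channels = c("F7", "F3", "Fz", "F4", "F8"),
                         preprocess = TRUE) {
  if (preprocess) eeg <- preprocess_eeg(eeg)
  epochs <- locate_epochs(eeg)
  cells <- average_cells(epoch_power_table(eeg, epochs, channels))
  list(cells = cells, gcsr = gcsr_spectrum(cells))
}
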