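# EEG cleaning: residual mains attenuation with a three-point running mean,
# eye-blink removal by least-squares template subtraction against Fp1, and
# amplitude-threshold artifact rejection to missing values.

#' Three-point running mean filter
#'
#' `y[n] = (x[n-1] + x[n] + x[n+1]) / 3`, with replicated endpoints.  At a
#' 128 Hz sampling rate the first null of its magnitude response,
#' `(1 + 2 cos(2 pi f / fs)) / 3`, falls at fs/3 ~ 42.7 Hz, attenuating
#' residual mains while leaving the 4-12 Hz band essentially untouched.
#'
#' @param x numeric sample vector (length >= 3).
#' @return filtered vector, same length.
#' @export
running_mean_filter <- function(x) {
  n <- length(x)
  if (n < 3) stop_config("running_mean_filter needs at least 3 samples")
  (c(x[1], x[-n]) + x + c(x[-1], x[n])) / 3
}

#' Detect eye blinks on the Fp1 channel
#'
#' Threshold-plus-shape detector: samples above `threshold_uv` are grouped
#' into candidate events, each event is anchored at its local peak, and a
#' window of one template length is laid around the peak.  Overlapping
#' windows are merged into one.
#'
#' @param fp1 Fp1 sample vector, uV.
#' @param fs sampling rate, Hz.
#' @param threshold_uv detection threshold (default 75 uV; blinks at Fp1 are
#'   an order of magnitude above background).
#' @param template_duration_s blink waveform length, s.
#' @param peak_frac position of the waveform peak within the template
#'   (fraction of its length; matches the stereotyped biphasic shape).
#' @return data.frame with `start`, `end` (sample indices) and `peak`.
#' @export
detect_blinks <- function(fp1, fs = FS_HZ, threshold_uv = 75,
                          template_duration_s = 0.3, peak_frac = 1 / 3) {
  len <- round(template_duration_s * fs)
  above <- which(!is.na(fp1) & fp1 > threshold_uv)
  if (length(above) == 0)
    return(data.frame(start = integer(0), end = integer(0), peak = integer(0)))
  # group threshold crossings separated by less than one template length
  grp <- cumsum(c(1L, diff(above) > len))
  windows <- do.call(rbind, lapply(split(above, grp), function(idx) {
    peak <- idx[which.max(fp1[idx])]
    start <- max(1L, peak - round(peak_frac * len) + 1L)
    data.frame(start = start, end = min(length(fp1), start + len - 1L),
               peak = peak)
  }))
  rownames(windows) <- NULL
  # merge overlaps
  if (nrow(windows) > 1) {
    keep <- list(windows[1, ])
    for (i in 2:nrow(windows)) {
      last <- keep[[length(keep)]]
      if (windows$start[i] <= last$end) {
        last$end <- max(last$end, windows$end[i])
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- windows[i, ]
    }
    windows <- do.call(rbind, keep)
    rownames(windows) <- NULL
  }
  windows
}

#' Build a blink template from detected Fp1 segments
#'
#' The ballistic blink waveform is estimated as the average of the detected
#' Fp1 segments, peak-aligned and peak-normalised to 1.
#'
#' @param fp1 Fp1 sample vector.
#' @param windows detection table from [detect_blinks()].
#' @param fs sampling rate, Hz.
#' @return list of class `blink_template`: `waveform` (unit peak), `peak`
#'   (sample index of the peak within the waveform).
#' @export
build_blink_template <- function(fp1, windows, fs = FS_HZ) {
  if (nrow(windows) == 0) stop_config("no blink windows to build template from")
  len <- max(windows$end - windows$start) + 1L
  segs <- lapply(seq_len(nrow(windows)), function(i) {
    s <- fp1[windows$start[i]:windows$end[i]]
    length(s) <- len  # pad with NA
    # align peaks to a common index
    shift <- which.max(s) - which.max(fp1[windows$start[1]:windows$end[1]])
    if (!is.na(shift) && shift != 0) {
      s <- if (shift > 0) c(s[-seq_len(shift)], rep(NA, shift))
           else c(rep(NA, -shift), s[seq_len(len + shift)])
    }
    s
  })
  w <- colMeans(do.call(rbind, segs), na.rm = TRUE)
  w[is.na(w)] <- 0
  w <- w / max(abs(w))
  structure(list(waveform = w, peak = which.max(abs(w))),
            class = "blink_template")
}

#' Remove blinks by scaled template subtraction
#'
#' For each blink window and each channel, the template `t` is scaled by the
#' least-squares coefficient `b* = <ch, t> / <t, t>` over the window and
#' subtracted.  Fp1 drives the fit and is cleaned too, though the analysis
#' channels are the point of the operation.
#'
#' @param eeg a `continuous_eeg`.
#' @param template a `blink_template`.
#' @param windows detection table from [detect_blinks()].
#' @return the `continuous_eeg` with blink components subtracted; provenance
#'   updated.
#' @export
remove_blinks <- function(eeg, template, windows) {
  w <- template$waveform
  if (sum(w^2) == 0) stop_config("zero-energy blink template")
  sig <- eeg$signal
  n <- nrow(sig)
  for (i in seq_len(nrow(windows))) {
    idx <- windows$start[i]:min(windows$start[i] + length(w) - 1L, n)
    tt <- w[seq_along(idx)]
    denom <- sum(tt^2)
    for (ch in seq_len(ncol(sig))) {
      seg <- sig[idx, ch]
      ok <- !is.na(seg)
      if (!any(ok)) next
      b <- sum(seg[ok] * tt[ok]) / sum(tt[ok]^2)
      sig[idx, ch] <- seg - b * tt
    }
  }
  eeg$signal <- sig
  eeg$provenance <- c(eeg$provenance,
                      sprintf("remove_blinks: %d windows", nrow(windows)))
  eeg
}

#' Replace large-amplitude artifacts with missing values
#'
#' Samples whose absolute value exceeds the threshold on any channel are
#' flagged, padded by `window_pad_s` on both sides, and set to NA on all
#' channels; the mask is recorded so downstream epoching can reject affected
#' trials.
#'
#' @param eeg a `continuous_eeg`.
#' @param amplitude_threshold_uv rejection threshold, uV (default 150).
#' @param window_pad_s padding around flagged samples, s (default 0.1).
#' @return the `continuous_eeg` with `rejection_mask` (logical per sample)
#'   and NA-filled signal in masked regions.
#' @export
reject_artifacts <- function(eeg, amplitude_threshold_uv = 150,
                             window_pad_s = 0.1) {
  stopifnot(amplitude_threshold_uv > 0)
  sig <- eeg$signal
  n <- nrow(sig)
  bad <- rowSums(abs(sig) > amplitude_threshold_uv, na.rm = TRUE) > 0
  pad <- round(window_pad_s * eeg$fs)
  if (any(bad) && pad > 0) {
    idx <- which(bad)
    for (k in idx) bad[max(1, k - pad):min(n, k + pad)] <- TRUE
  }
  bad <- bad | rowSums(is.na(sig)) > 0
  sig[bad, ] <- NA_real_
  eeg$signal <- sig
  eeg$rejection_mask <- bad
  eeg$provenance <- c(eeg$provenance,
                      sprintf("reject_artifacts: %d samples (%.1f%%) masked",
                              sum(bad), 100 * mean(bad)))
  eeg
}

#' Full preprocessing pass
#'
#' Applies, in order: the three-point running mean (residual mains), blink
#' detection + template construction + least-squares subtraction, and
#' amplitude-threshold artifact rejection.
#'
#' @param eeg a `continuous_eeg`.
#' @param blink_threshold_uv blink detection threshold, uV.
#' @param artifact_threshold_uv rejection threshold, uV.
#' @param artifact_pad_s rejection padding, s.
#' @return cleaned `continuous_eeg` with `rejection_mask` and `provenance`.
#' @export
preprocess_eeg <- function(eeg, blink_threshold_uv = 75,
                           artifact_threshold_uv = 150,
                           artifact_pad_s = 0.1) {
  for (ch in seq_len(ncol(eeg$signal)))
    eeg$signal[, ch] <- running_mean_filter(eeg$signal[, ch])
  eeg$provenance <- c(eeg$provenance, "running_mean_filter")
  fp1 <- eeg$signal[, "Fp1"]
  windows <- detect_blinks(fp1, eeg$fs, threshold_uv = blink_threshold_uv)
  if (nrow(windows) > 0) {
    tmpl <- build_blink_template(fp1, windows, eeg$fs)
    eeg <- remove_blinks(eeg, tmpl, windows)
  }
  reject_artifacts(eeg, artifact_threshold_uv, artifact_pad_s)
}
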