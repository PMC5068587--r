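# Synthetic continuous EEG: 1/f ("pink") background, residual mains, eye-blink
# transients, and a band-limited goal-conflict burst injected on medium-SSD
# stop trials at one target channel.  The generator defines the study
# conditions every downstream stage is tested against.

#' EEG recording parameters
#'
#' @param fs sampling rate, Hz (the analysis assumes 128).
#' @param channels channel labels; must include Fp1 (blink reference) and the
#'   frontal analysis row F7, F3, Fz, F4, F8.
#' @param pink_noise_scale RMS of the 1/f background per channel, uV.
#' @param mains_hz,mains_amp residual mains frequency (Hz) and amplitude (uV).
#' @param blink_rate mean blink rate, per minute.
#' @param blink_amp_fp1 blink peak amplitude at Fp1, uV.
#' @param blink_propagation named per-channel scale factors relative to Fp1
#'   (decaying anteriorly-to-laterally).
#' @param band_pass recording band pass, Hz.
#' @return list of class `eeg_params`.
#' @export
eeg_params <- function(fs = FS_HZ, channels = CHANNELS,
                       pink_noise_scale = 10, mains_hz = 50, mains_amp = 2,
                       blink_rate = 15, blink_amp_fp1 = 150,
                       blink_propagation = c(Fp1 = 1, F7 = 0.35, F3 = 0.45,
                                             Fz = 0.5, F4 = 0.45, F8 = 0.35),
                       band_pass = c(1, 36)) {
  stopifnot(fs == FS_HZ, all(c("Fp1", "F7", "F3", "Fz", "F4", "F8") %in% channels),
            band_pass[1] > 0, band_pass[2] < fs / 2)
  structure(list(fs = fs, channels = channels,
                 pink_noise_scale = pink_noise_scale,
                 mains_hz = mains_hz, mains_amp = mains_amp,
                 blink_rate = blink_rate, blink_amp_fp1 = blink_amp_fp1,
                 blink_propagation = blink_propagation,
                 band_pass = band_pass),
            class = "eeg_params")
}

#' Conflict-burst injection parameters
#'
#' A band-limited (default 4-12 Hz) amplitude-modulated burst is added on the
#' target channel during the 1 s analysis window (starting 0.25 s before the
#' stop signal) of every medium-staircase stop trial.  A Hanning-shaped
#' envelope concentrates the injected power where the analysis window is
#' maximally sensitive.
#'
#' @param amplitude RMS of the enveloped burst over its 1 s window, uV.
#' @param band frequency band (Hz); component sinusoids at 1 Hz spacing.
#' @param target_channel channel receiving the burst (default F8).
#' @param block_profile per-block amplitude multipliers; the default (1, 0, 1)
#'   mimics conflict rhythmicity appearing in blocks 1 and 3 but not 2.
#' @param drug_multiplier group-level amplitude factor in [0, 1].
#' @param trait_coupling slope linking a participant's standardised
#'   neuroticism score to burst amplitude (0 = no coupling).
#' @return list of class `conflict_injection`.
#' @export
conflict_injection <- function(amplitude = 5, band = c(4, 12),
                               target_channel = "F8",
                               block_profile = c(1, 0, 1),
                               drug_multiplier = 1, trait_coupling = 0) {
  stopifnot(amplitude >= 0, band[1] <= band[2], drug_multiplier >= 0)
  structure(list(amplitude = amplitude, band = band,
                 target_channel = target_channel,
                 block_profile = block_profile,
                 drug_multiplier = drug_multiplier,
                 trait_coupling = trait_coupling),
            class = "conflict_injection")
}

# 1/f-amplitude noise of unit RMS via spectral shaping of white noise.
pink_noise <- function(n, fs) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, 1 / sqrt(f[-1]))
  y <- Re(fft(X * shape, inverse = TRUE)) / n
  y / sd(y)
}

# Stereotyped biphasic blink waveform, 300 ms, peak-normalised to 1.
blink_template_shape <- function(fs = FS_HZ, duration_s = 0.3) {
  t <- seq(0, by = 1 / fs, length.out = round(duration_s * fs))
  h <- exp(-((t - 0.10) / 0.045)^2) - 0.35 * exp(-((t - 0.22) / 0.06)^2)
  h / max(abs(h))
}

# Trial timeline: fixed trial spacing; the arrow (go stimulus) appears 0.5 s
# after trial onset.  All onsets land on the sample grid.
trial_timeline <- function(n_trials, fs = FS_HZ, trial_spacing_s = 2.5,
                           fixation_s = 0.5) {
  onset <- (seq_len(n_trials) - 1) * trial_spacing_s
  list(trial_onset_s = onset, arrow_onset_s = onset + fixation_s,
       duration_s = n_trials * trial_spacing_s + 2)
}

#' Synthesise a continuous EEG record for one behavioural session
#'
#' The record is the sum of pink noise, a residual mains sinusoid, stereotyped
#' blink transients (full amplitude at Fp1, scaled copies elsewhere), and the
#' conflict burst on the target channel during each medium-SSD stop trial's
#' analysis window; the whole record is then band-passed (zero-phase
#' Butterworth) to the recording band.  Stop-signal event times are realised
#' on the sample grid, so the emitted event table carries the realised SSD.
#'
#' @param behavior a `behavioral_record` from [simulate_behavior()].
#' @param eeg an `eeg_params`.
#' @param inj a `conflict_injection`.
#' @param seed integer seed (independent substreams for noise, blinks and
#'   burst phases).
#' @param gain extra amplitude multiplier applied on top of
#'   `drug_multiplier` (used for trait coupling at the cohort level).
#' @param keep_components if TRUE, attach the pre-band-pass injected component
#'   as attribute `"injected"` (for energy-accounting diagnostics).
#' @return list of class `continuous_eeg`: `signal` (samples x channels
#'   matrix, uV), `fs`, `channels`, `events` (one row per trial: `index`,
#'   `block`, `onset_s` = arrow onset, `stop_onset_s`, `ssd_ms` realised on
#'   the sample grid, `trial_type`, `staircase`, `outcome`).
#' @export
synthesize_eeg <- function(behavior, eeg = eeg_params(),
                           inj = conflict_injection(), seed = 1,
                           gain = 1, keep_components = FALSE) {
  tr <- behavior$trials
  fs <- eeg$fs
  tl <- trial_timeline(nrow(tr), fs)
  n <- round(tl$duration_s * fs)
  nch <- length(eeg$channels)
  t_sec <- (seq_len(n) - 1) / fs

  # events: stop onsets snapped to the sample grid
  is_stop <- tr$kind == "stop"
  stop_onset <- rep(NA_real_, nrow(tr))
  stop_onset[is_stop] <- round((tl$arrow_onset_s[is_stop] +
                                  tr$ssd_ms[is_stop] / 1000) * fs) / fs
  events <- data.frame(
    index = tr$index, block = tr$block,
    onset_s = tl$arrow_onset_s,
    stop_onset_s = stop_onset,
    ssd_ms = (stop_onset - tl$arrow_onset_s) * 1000,
    trial_type = tr$kind, staircase = tr$staircase,
    outcome = ifelse(is_stop, ifelse(tr$stop_success, "inhibit", "respond"),
                     ifelse(tr$responded & tr$correct %in% TRUE,
                            "correct", "error")),
    stringsAsFactors = FALSE)

  sig <- matrix(0, n, nch, dimnames = list(NULL, eeg$channels))

  if (eeg$pink_noise_scale > 0) {
    noise <- with_substream(seed, "noise", {
      vapply(seq_len(nch), function(ch) pink_noise(n, fs), numeric(n))
    })
    sig <- sig + eeg$pink_noise_scale * noise
  }
  if (eeg$mains_amp > 0)
    sig <- sig + eeg$mains_amp * sin(2 * pi * eeg$mains_hz * t_sec)

  if (eeg$blink_rate > 0 && eeg$blink_amp_fp1 > 0) {
    tmpl <- blink_template_shape(fs)
    blinks <- with_substream(seed, "blinks", {
      nb <- rpois(1, eeg$blink_rate * tl$duration_s / 60)
      list(at = sort(ceiling(runif(nb, 0, n - length(tmpl) - 1))),
           amp = runif(nb, 0.8, 1.2) * eeg$blink_amp_fp1)
    })
    prop <- eeg$blink_propagation[eeg$channels]
    for (b in seq_along(blinks$at)) {
      idx <- blinks$at[b] + seq_along(tmpl) - 1L
      sig[idx, ] <- sig[idx, ] + outer(tmpl * blinks$amp[b], prop)
    }
  }

  injected <- NULL
  med_stop <- which(is_stop & tr$staircase == "medium")
  amp_eff <- inj$amplitude * inj$drug_multiplier * gain
  if (amp_eff > 0 && length(med_stop) > 0) {
    win_len <- fs  # 1 s
    env <- 0.5 * (1 - cos(2 * pi * (seq_len(win_len) - 1) / (win_len - 1)))
    freqs <- seq(inj$band[1], inj$band[2], by = 1)
    # rhythmicity is strongest mid-band (5-9 Hz), tapering to the band edges
    amps <- if (length(freqs) > 1) {
      0.2 + 0.8 * 0.5 * (1 - cos(2 * pi * (seq_along(freqs) - 1) /
                                   (length(freqs) - 1)))
    } else 1
    inj_sig <- numeric(n)
    with_substream(seed, "injection", {
      for (i in med_stop) {
        blk_mult <- inj$block_profile[tr$block[i]]
        if (blk_mult == 0) next
        start <- round((stop_onset[i] - 0.25) * fs) + 1L
        idx <- start + seq_len(win_len) - 1L
        if (start < 1 || idx[win_len] > n) next
        phases <- runif(length(freqs), 0, 2 * pi)
        tt <- (idx - 1) / fs
        raw <- rowSums(vapply(seq_along(freqs), function(k)
          amps[k] * sin(2 * pi * freqs[k] * tt + phases[k]),
          numeric(win_len)))
        burst <- env * raw
        burst <- burst / sqrt(mean(burst^2)) * amp_eff * blk_mult
        inj_sig[idx] <- inj_sig[idx] + burst
      }
    })
    sig[, inj$target_channel] <- sig[, inj$target_channel] + inj_sig
    injected <- inj_sig
  }

  # recording band pass (zero-phase, applied to the whole record)
  bf <- signal::butter(4, eeg$band_pass / (fs / 2), type = "pass")
  for (ch in seq_len(nch))
    sig[, ch] <- signal::filtfilt(bf, sig[, ch])

  out <- structure(list(signal = sig, fs = fs, channels = eeg$channels,
                        events = events),
                   class = "continuous_eeg")
  if (keep_components) attr(out, "injected") <- injected
  out
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples (%.1f s at %d Hz); %d events\n",
              ncol(x$signal), nrow(x$signal), nrow(x$signal) / x$fs, x$fs,
              nrow(x$events)))
  invisible(x)
}
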