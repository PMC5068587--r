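---
title: "Methods: goal-conflict-specific rhythmicity in a three-staircase stop-signal task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: goal-conflict-specific rhythmicity in a three-staircase stop-signal task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gcsr)
```

This vignette documents the scientific model behind the package and the
design decisions baked into its defaults. The code chunks are illustrative
and not evaluated when the vignette is built.

## The biomarker

Goal-conflict-specific rhythmicity (GCSR) is a candidate EEG biomarker of an
anxiety-related conflict-detection process. The theory behind it holds that
a dedicated behavioural-inhibition system is engaged specifically when two
goals of comparable strength compete — not merely when a response must be
withheld — and that its engagement is visible as 4–12 Hz rhythmical activity
over right lateral frontal cortex (electrode F8 in the 10–20 system), the
human analogue of rodent hippocampal rhythmical slow activity.

To isolate *conflict-specific* activity, the stop-signal task is run with
three interleaved stop-signal-delay (SSD) staircases:

- a **short** SSD (20% of the recent mean Go RT), where stopping is easy and
  almost always succeeds — the "stop" goal dominates;
- a **long** SSD (80% of the recent mean Go RT), where stopping almost
  always fails — the "go" goal dominates;
- a **medium** tracking staircase converging on ~50% inhibition, where going
  and stopping are balanced — maximal goal conflict.

GCSR at each frequency f is the double difference

> GCSR(f) = [Stop − Go](medium) − ½ { [Stop − Go](short) + [Stop − Go](long) }

of mean log spectral power, i.e. the quadratic contrast over SSD level of
the Stop–Go difference. Stimulus, motor and generic inhibition effects are
common to all three SSD levels and cancel; what survives is activity
specific to the balanced-conflict condition.

## Task design

A session is 3 blocks × 128 trials. Each disjoint window of four trials
contains exactly one stop trial at a random position, giving 32 stop and
96 go trials per block; left/right go arrows are balanced within block. The
32 stop trials per session per staircase arise from a rotated base
assignment, so per-block staircase counts are (11, 11, 10) up to rotation.

The medium staircase starts at 45% of the pretest Go RT and moves in 30 ms
steps — up after a successful stop (making the next stop harder), down after
a failure. A proposed medium SSD is never allowed within 50 ms of the
concurrent short or long SSD: a conflicting proposal is moved to the 50 ms
boundary on the side of the conflicting staircase where it lies, and SSDs
are floored at 0. Trial feedback is a smiley/frowney face, with an
additional "too slow" flag when a Go RT exceeds 1.5× the pretest mean — this
discourages the strategic slowing that would otherwise let participants beat
the staircases.

### Where the medium staircase actually operates

An unconstrained up/down staircase with equal step sizes converges on 50%
inhibition. The 50 ms separation rule breaks that symmetry: near the short
staircase (which sits at ~20% of Go RT), failed-stop decrements are
truncated at `short + 50` ms while success increments are not, so failures
outnumber successes slightly and the equilibrium sits a little below 50%.
With the default responder the cohort mean is ~47% successful stops on the
medium staircase. This is a structural property of the staircase rules
themselves, not a bug: the package reports it honestly rather than
re-centring the staircase.

## The behavioural simulator

Behaviour follows the independent horse-race model: a stop succeeds iff
`SSD + SSRT < Go RT`, where SSRT is the latency of the inhibitory process.
Go RTs are ex-Gaussian (Normal(µ, σ) + Exponential(τ), truncated at 150 ms);
SSRTs are Gaussian truncated at 50 ms. The default parameters
(µ = 375, σ = 90, τ = 50 ms; SSRT 240 ± 50 ms) were calibrated once, before
any test was written, against the behavioural profile the task is designed
to produce — ~80% inhibition on the short staircase, ~50% on medium, ~10%
on long, mean Go RT ≈ 425 ms and SSRT ≈ 240 ms — and then frozen. The SSRT
estimate used throughout is median Go RT minus mean medium SSD.

## The synthetic EEG generator

Six channels (Fp1, F7, F3, Fz, F4, F8) at 128 Hz, built from independent
named random substreams so each component is separately reproducible:

- **pink (1/f) background**, synthesized by shaping white noise in the
  frequency domain;
- **50 Hz mains** at low amplitude;
- **eye blinks**: a biphasic 300 ms template (positive lobe at 0.10 s,
  smaller negative lobe at 0.22 s), ~15/min, 150 µV at Fp1, propagated to
  frontal channels with fixed attenuation (F8 and F7 at 0.35);
- **conflict bursts**: the ground-truth GCSR signal. On medium-staircase
  stop trials only, a 1 s Hann-enveloped 4–12 Hz burst is added at F8
  starting 0.25 s before the stop signal. Component amplitudes follow a
  Hann profile over the band (peaking mid-band near 7–9 Hz) rather than a
  flat profile: a flat spectrum has no curvature over the band, which would
  make the frequency-polynomial contrasts used downstream nearly blind to
  it, and mid-band-peaked conflict activity is also the physiologically
  realistic shape. Each burst is RMS-normalised to the configured
  amplitude, then scaled by a per-block profile (default 1, 0, 1 — the
  effect habituates mid-session and returns), a drug multiplier
  (anxiolytics attenuate it), and an optional trait-coupled gain.

The whole record is band-passed 1–36 Hz (4th-order Butterworth, forward and
reverse). Records can be written to EDF (a minimal 16-bit writer/reader is
included, since no EDF package is available in the target environment) with
a BIDS-style events TSV.

## Preprocessing

- A **3-point running mean** smooths the record; at 128 Hz its first
  spectral null is at fs/3 ≈ 43 Hz, so it strongly attenuates residual
  mains while leaving the 4–12 Hz band nearly untouched.
- **Blink handling** follows the template-subtraction logic: blinks are
  detected on Fp1 by threshold crossing (75 µV), a participant-specific
  template is built by peak-aligned averaging, and for every blink window
  and channel the least-squares scale of the template is subtracted. This
  preserves underlying EEG that is orthogonal to the blink waveform,
  unlike naive epoch rejection.
- Remaining samples exceeding ±150 µV on any channel are masked to NA with
  0.1 s padding; epochs containing NA are rejected downstream.

## Spectral extraction

Every stop trial yields a 1 s epoch starting 0.25 s before the stop signal,
and a matched go epoch from the nearest preceding go trial, positioned at
its arrow onset plus the same SSD minus 0.25 s — so the go epoch covers the
moment a stop signal *would* have occurred. Each 128-sample epoch is Hann
tapered and Fourier transformed; power at the 1 Hz bins 4–12 Hz is
log-transformed with a 10⁻¹² floor. Log power is averaged per
(block × channel × Stop/Go × SSD level × frequency) cell, and the GCSR
double difference above is formed per block, channel and frequency.

## Statistics

Inference uses single-df orthogonal contrasts rather than omnibus ANOVA:

- integer orthogonal polynomial weights over the 9 frequency bins (linear,
  quadratic, cubic);
- a composite per-participant score: Stop–Go (+1, −1) × SSD quadratic
  (−½, 1, −½) × frequency polynomial, summed over the 54 cells of one
  block × channel;
- a one-sample t test of the scores against zero (reported as F = t² on
  1, n−1 df), and a one-way ANOVA across drug groups;
- per-frequency Pearson correlations between GCSR and questionnaire traits;
- classical forward stepwise regression (F-to-enter, p < 0.05, no removal)
  of traits on the 9 block-1 GCSR frequencies.

Note the sign logic of the composite: the injected conflict spectrum is an
inverted U over 4–12 Hz, so its frequency-*quadratic* composite (positive
weights at the band edges, negative mid-band) is reliably **negative**,
while the odd-order composites are near zero for a symmetric spectrum.

Because the composite is a fixed linear functional of noisy cell means, its
type-I error can be checked by direct Monte Carlo:
`simulate_null_contrast_scores()` pushes white-noise epochs through the same
Hann/FFT log-power path in vectorised form (one epoch per cell — more epochs
only shrink cell noise without changing the null calibration) and measures
the rejection rate at α = 0.05. At the default 34 participants per cohort
the measured rate sits within [0.04, 0.06] over 10,000 cohorts.

## Problem sizes and runtimes

A full simulated participant (3 × 128 trials, 6 channels, ~16 min of
record) synthesises and analyses in roughly a second; the default
34-participant pipeline (`run_pipeline(default_run_config())`) takes about
a minute. The bundled test-suite fixtures use 3 × 32-trial blocks where only
structure, not power, is being checked.

## Limitations

The generator is a measurement model, not a brain model: it reproduces the
spectral, spatial and pharmacological *signatures* of the biomarker (band,
channel gradient, block profile, drug attenuation, trait coupling) without
modelling cortical dynamics. Omnibus F statistics from human cohorts are
not reproducible from synthetic data and are treated only as structural
references; the package's claims are calibration (null behaviour
of the tests) and recovery (injected effects are detected with the correct
sign, site and ordering).
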