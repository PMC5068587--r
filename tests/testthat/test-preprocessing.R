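test_that("running mean has unit DC gain and its first null near 43 Hz", {
  expect_equal(running_mean_filter(rep(7, 10)), rep(7, 10))
  expect_equal(running_mean_filter(c(0, 3, 0)), c(1, 1, 1))
  expect_error(running_mean_filter(c(1, 2)), "at least 3")
  # first null at fs/3 ~ 42.67 Hz: interior output vanishes exactly
  x <- sin(2 * pi * (128 / 3) * (0:383) / 128)
  y <- running_mean_filter(x)
  expect_lt(max(abs(y[5:380])), 1e-12)
})

test_that("running mean is linear with the closed-form magnitude response", {
  set.seed(6)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(running_mean_filter(2 * a + 3 * b),
               2 * running_mean_filter(a) + 3 * running_mean_filter(b))
  fs <- 128
  for (f in c(4, 10, 25, 50)) {
    n <- 0:511
    x <- cos(2 * pi * f * n / fs)
    y <- running_mean_filter(x)[10:500]
    # amplitude via projection on the quadrature pair
    n2 <- n[10:500]
    amp <- sqrt((2 * mean(y * cos(2 * pi * f * n2 / fs)))^2 +
                  (2 * mean(y * sin(2 * pi * f * n2 / fs)))^2)
    expect_equal(amp, abs((1 + 2 * cos(2 * pi * f / fs)) / 3),
                 tolerance = 0.01)
  }
})

make_blink_record <- function(positions, amps, n = 6000, noise_sd = 0,
                              seed = 1) {
  set.seed(seed)
  tmpl <- gcsr:::blink_template_shape()
  prop <- c(Fp1 = 1, F7 = 0.35, F3 = 0.45, Fz = 0.5, F4 = 0.45, F8 = 0.35)
  sig <- matrix(rnorm(n * 6, sd = noise_sd), n, 6,
                dimnames = list(NULL, names(prop)))
  blink <- matrix(0, n, 6, dimnames = list(NULL, names(prop)))
  for (i in seq_along(positions)) {
    idx <- positions[i] + seq_along(tmpl) - 1L
    blink[idx, ] <- blink[idx, ] + outer(tmpl * amps[i], prop)
  }
  list(eeg = eeg_stub(sig + blink), blink = blink, template = tmpl)
}

test_that("the detector finds exactly the injected blinks", {
  pos <- seq(200, 5500, length.out = 12)
  rec <- make_blink_record(round(pos), rep(150, 12))
  det <- detect_blinks(rec$eeg$signal[, "Fp1"])
  expect_equal(nrow(det), 12)
  # blink-free record: no detections
  expect_equal(nrow(detect_blinks(rnorm(6000, sd = 10))), 0)
  # two blinks closer than a template length merge into one window
  rec2 <- make_blink_record(c(1000, 1015), c(150, 150))
  expect_equal(nrow(detect_blinks(rec2$eeg$signal[, "Fp1"])), 1)
})

test_that("least-squares template subtraction recovers exact fits", {
  tmpl_shape <- gcsr:::blink_template_shape()
  tmpl <- structure(list(waveform = tmpl_shape,
                         peak = which.max(abs(tmpl_shape))),
                    class = "blink_template")
  n <- 500
  sig <- matrix(0, n, 2, dimnames = list(NULL, c("Fp1", "F8")))
  sig[101:(100 + length(tmpl_shape)), "F8"] <- 0.5 * tmpl_shape
  windows <- data.frame(start = 101, end = 100 + length(tmpl_shape),
                        peak = 101)
  cleaned <- remove_blinks(eeg_stub(sig), tmpl, windows)
  expect_lt(max(abs(cleaned$signal[, "F8"])), 1e-12)
  # a segment orthogonal to the template is untouched
  u <- seq_along(tmpl_shape)
  ortho <- u - sum(u * tmpl_shape) / sum(tmpl_shape^2) * tmpl_shape
  sig2 <- matrix(0, n, 2, dimnames = list(NULL, c("Fp1", "F8")))
  sig2[101:(100 + length(tmpl_shape)), "F8"] <- ortho
  cleaned2 <- remove_blinks(eeg_stub(sig2), tmpl, windows)
  expect_equal(cleaned2$signal, sig2, tolerance = 1e-12)
  expect_error(remove_blinks(eeg_stub(sig),
                             structure(list(waveform = rep(0, 10), peak = 1),
                                       class = "blink_template"),
                             windows), "zero-energy")
})

test_that("per-channel blink scales are recovered in a noise-free fixture", {
  pos <- c(500, 1500, 2500)
  rec <- make_blink_record(pos, c(120, 150, 180))
  det <- detect_blinks(rec$eeg$signal[, "Fp1"])
  tmpl <- build_blink_template(rec$eeg$signal[, "Fp1"], det)
  w <- tmpl$waveform
  idx <- det$start[2]:det$end[2]
  seg <- rec$eeg$signal[idx, "F8"]
  b <- sum(seg * w[seq_along(idx)]) / sum(w[seq_along(idx)]^2)
  expect_equal(b, 150 * 0.35, tolerance = 0.02)
})

test_that("blink removal leaves <10% of blink power at F8, and residuals are
          LS-optimal", {
  pos <- round(seq(300, 5600, length.out = 10))
  rec <- make_blink_record(pos, runif(10, 120, 180), noise_sd = 10, seed = 4)
  det <- detect_blinks(rec$eeg$signal[, "Fp1"])
  tmpl <- build_blink_template(rec$eeg$signal[, "Fp1"], det)
  cleaned <- remove_blinks(rec$eeg, tmpl, det)
  resid_blink <- cleaned$signal[, "F8"] -
    (rec$eeg$signal[, "F8"] - rec$blink[, "F8"])
  in_win <- unlist(lapply(seq_len(nrow(det)),
                          function(i) det$start[i]:det$end[i]))
  expect_lt(sum(resid_blink[in_win]^2) / sum(rec$blink[in_win, "F8"]^2), 0.1)
  # optimality: the residual in each fitted window is orthogonal to the
  # template, so no other scale can reduce the squared error
  w <- tmpl$waveform
  for (i in seq_len(nrow(det))) {
    idx <- det$start[i]:det$end[i]
    expect_lt(abs(sum(cleaned$signal[idx, "F8"] * w[seq_along(idx)])) /
                sqrt(sum(w[seq_along(idx)]^2)), 1e-6)
  }
})

test_that("artifact rejection masks spikes with padding and is idempotent", {
  set.seed(8)
  sig <- matrix(rnorm(1280 * 3, sd = 10), 1280, 3,
                dimnames = list(NULL, c("Fp1", "F7", "F8")))
  clean <- reject_artifacts(eeg_stub(sig), 150, 0.1)
  expect_equal(sum(clean$rejection_mask), 0)
  sig[640, "F7"] <- 500
  spiked <- reject_artifacts(eeg_stub(sig), 150, 0.1)
  pad <- round(0.1 * 128)
  expect_equal(which(spiked$rejection_mask), (640 - pad):(640 + pad))
  expect_true(all(is.na(spiked$signal[640, ])))
  # all-missing input comes back unchanged with a full mask
  sig_na <- matrix(NA_real_, 100, 2, dimnames = list(NULL, c("Fp1", "F8")))
  full <- reject_artifacts(eeg_stub(sig_na), 150, 0)
  expect_true(all(full$rejection_mask))
  expect_true(all(is.na(full$signal)))
})
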