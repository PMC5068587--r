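test_that("epoch windows sit 0.25 s before the stop signal", {
  events <- data.frame(
    index = 1:2, block = 1,
    onset_s = c(95.0, 99.5),
    stop_onset_s = c(NA, 100.0),
    ssd_ms = c(NA, 500),
    trial_type = c("go", "stop"),
    staircase = c(NA, "medium"),
    outcome = c("correct", "inhibit"), stringsAsFactors = FALSE)
  eeg <- eeg_stub(matrix(0, 128 * 110, 1, dimnames = list(NULL, "F8")),
                  events)
  ep <- locate_epochs(eeg)
  expect_equal(nrow(ep), 2)
  stop_ep <- ep[ep$trial_type == "stop", ]
  expect_equal(stop_ep$start_s, 99.75)
  expect_equal(stop_ep$start_sample, round(99.75 * 128) + 1)
  # matched go: arrow onset 95.0 + SSD 0.5 - 0.25 = 95.25
  go_ep <- ep[ep$trial_type == "matched_go", ]
  expect_equal(go_ep$start_s, 95.25)
  expect_equal(go_ep$ssd_level, "medium")
})

test_that("a full session yields two epochs per retained stop trial", {
  fx <- default_session()
  ep <- locate_epochs(fx$eeg)
  n_stop <- sum(fx$behavior$trials$kind == "stop")
  expect_equal(nrow(ep), 2 * n_stop)
  expect_equal(sum(ep$trial_type == "stop"),
               sum(ep$trial_type == "matched_go"))
})

test_that("Hanning log power shows the expected tone peak and leakage", {
  ep <- sin(2 * pi * 8 * (0:127) / 128)
  lp <- hann_log_power(ep)
  p <- exp(lp)
  expect_equal(names(which.max(p)), "8Hz")
  # one-sided power of a unit tone through the symmetric Hann taper is
  # close to 1/8, with ~1/4 of the peak leaking into each adjacent bin
  expect_equal(unname(p["8Hz"]), 1 / 8, tolerance = 0.03)
  expect_equal(unname(p["7Hz"] / p["8Hz"]), 0.25, tolerance = 0.05)
  expect_equal(unname(p["9Hz"] / p["8Hz"]), 0.25, tolerance = 0.05)
  expect_lt(unname(p["6Hz"] / p["8Hz"]), 1e-4)
  expect_lt(unname(p["11Hz"] / p["8Hz"]), 1e-4)
})

test_that("silent and missing epochs are handled explicitly", {
  lp0 <- hann_log_power(rep(0, 128))
  expect_equal(unname(lp0), rep(log(1e-12), 9))
  with_na <- rnorm(128); with_na[60] <- NA
  expect_true(all(is.na(hann_log_power(with_na))))
  expect_error(hann_log_power(rnorm(100)), "128 samples")
})

test_that("the FFT path matches a direct O(N^2) DFT oracle", {
  set.seed(10)
  for (i in 1:100) {
    ep <- rnorm(128, sd = runif(1, 0.1, 20))
    expect_equal(unname(hann_log_power(ep)), oracle_dft_log_power(ep),
                 tolerance = 1e-9)
  }
})

test_that("the matrix spectral path equals the scalar path", {
  set.seed(11)
  E <- matrix(rnorm(128 * 50), 128, 50)
  L <- gcsr:::hann_log_power_matrix(E)
  for (j in seq_len(50))
    expect_equal(unname(L[, j]), unname(hann_log_power(E[, j])),
                 tolerance = 1e-12)
})

test_that("cell averaging matches a brute-force group-by mean", {
  set.seed(12)
  ep_tab <- expand.grid(trial_index = 1:12, channel = c("F8", "Fz"),
                        freq_hz = 4:12, stringsAsFactors = FALSE)
  ep_tab$block <- ifelse(ep_tab$trial_index <= 6, 1, 2)
  ep_tab$trial_type <- c("stop", "go")[1 + ep_tab$trial_index %% 2]
  ep_tab$ssd_level <- c("short", "medium", "long")[1 + ep_tab$trial_index %% 3]
  ep_tab$log_power <- rnorm(nrow(ep_tab))
  cells <- average_cells(ep_tab)
  # brute force over a few random cells
  for (k in sample(nrow(cells), 20)) {
    row <- cells[k, ]
    sel <- ep_tab$block == row$block & ep_tab$channel == row$channel &
      ep_tab$trial_type == row$trial_type &
      ep_tab$ssd_level == row$ssd_level & ep_tab$freq_hz == row$freq_hz
    if (row$n_trials == 0) {
      expect_true(is.na(row$mean_log_power))
      expect_equal(sum(sel), 0)
    } else {
      expect_equal(row$mean_log_power, mean(ep_tab$log_power[sel]))
      expect_equal(row$n_trials, sum(sel))
    }
  }
  # idempotence: averaging two identical spectra gives the spectrum back
  two <- ep_tab[rep(1, 2), ]
  expect_equal(average_cells(two)$mean_log_power[
    !is.na(average_cells(two)$mean_log_power)], ep_tab$log_power[1])
})

test_that("the conflict contrast nulls flat inputs and scores unit effects", {
  base <- random_cells(13)
  flat <- base; flat$mean_log_power <- 2.5
  expect_equal(gcsr_spectrum(flat)$gcsr, rep(0, 9))
  # D(medium) = 1, D(short) = D(long) = 0 at one frequency
  unit <- flat
  unit$mean_log_power[unit$trial_type == "stop" &
                        unit$ssd_level == "medium" &
                        unit$freq_hz == 7] <- 3.5
  g <- gcsr_spectrum(unit)
  expect_equal(g$gcsr[g$freq_hz == 7], 1)
  expect_equal(g$gcsr[g$freq_hz != 7], rep(0, 8))
  # invariance to a grand additive offset
  shifted <- base; shifted$mean_log_power <- shifted$mean_log_power + 10
  expect_equal(gcsr_spectrum(shifted)$gcsr, gcsr_spectrum(base)$gcsr)
  # a missing contributing cell makes the output missing
  holed <- base
  holed$mean_log_power[holed$trial_type == "go" &
                         holed$ssd_level == "long" &
                         holed$freq_hz == 5] <- NA
  gh <- gcsr_spectrum(holed)
  expect_true(is.na(gh$gcsr[gh$freq_hz == 5]))
  expect_false(anyNA(gh$gcsr[gh$freq_hz != 5]))
})

test_that("injection at F8 produces the largest GCSR at F8", {
  fx <- default_session()
  ex <- extract_gcsr(fx$eeg)
  g <- ex$gcsr[ex$gcsr$block %in% c(1, 3), ]
  ch_means <- tapply(g$gcsr, g$channel, mean, na.rm = TRUE)
  for (other in c("F7", "F3", "Fz", "F4"))
    expect_gt(ch_means[["F8"]], ch_means[[other]])
  # and the block profile suppresses block 2
  g8 <- ex$gcsr[ex$gcsr$channel == "F8", ]
  by_block <- tapply(g8$gcsr, g8$block, mean, na.rm = TRUE)
  expect_gt(by_block[["1"]], by_block[["2"]])
  expect_gt(by_block[["3"]], by_block[["2"]])
})
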