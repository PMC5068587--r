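# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

# One fully simulated participant (default conditions) reused by several
# extraction and preprocessing tests.
default_session <- function(seed = 42, inj = conflict_injection()) {
  key <- sprintf("session-%d-%s", seed, paste(inj$amplitude, collapse = "-"))
  if (is.null(.fixtures[[key]])) {
    sched <- build_session_schedule(seed = seed)
    beh <- simulate_behavior(sched, seed = seed)
    .fixtures[[key]] <- list(schedule = sched, behavior = beh,
                             eeg = synthesize_eeg(beh, inj = inj, seed = seed))
  }
  .fixtures[[key]]
}

# Minimal continuous_eeg stub for functions that only need signal + events.
eeg_stub <- function(signal, events = NULL, fs = 128) {
  structure(list(signal = signal, fs = fs,
                 channels = colnames(signal), events = events),
            class = "continuous_eeg")
}

# Independent O(N^2) DFT log-power oracle (same taper and normalisation,
# computed without fft()).
oracle_dft_log_power <- function(epoch, floor_eps = 1e-12) {
  N <- length(epoch)
  h <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
  x <- h * epoch
  n <- 0:(N - 1)
  vapply(4:12, function(f) {
    re <- sum(x * cos(2 * pi * f * n / N))
    im <- -sum(x * sin(2 * pi * f * n / N))
    log(max(2 * (re^2 + im^2) / N^2, floor_eps))
  }, numeric(1))
}

# Random full 2 x 3 x 9 cell table for contrast tests.
random_cells <- function(seed, participant = "sub-001", block = 1,
                         channel = "F8") {
  set.seed(seed)
  g <- expand.grid(participant = participant, block = block,
                   channel = channel,
                   trial_type = c("stop", "go"),
                   ssd_level = c("short", "medium", "long"),
                   freq_hz = 4:12, stringsAsFactors = FALSE)
  g$mean_log_power <- rnorm(nrow(g))
  g$n_trials <- 10L
  g
}
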