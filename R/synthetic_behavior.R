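# Race-model responder: ex-Gaussian Go process racing an independent Gaussian
# stop process.  Defaults are calibrated to the cohort-level behavioural
# summaries of the three-staircase task (mean Go RT ~425 ms, SSRT ~240 ms,
# ~50% inhibition on the tracking staircase).

#' Responder model parameters
#'
#' Go RTs are ex-Gaussian (Gaussian mu/sigma plus exponential tau), truncated
#' at 150 ms; stop-signal reaction times are Gaussian truncated at 50 ms.
#' Defaults give mean Go RT = mu + tau = 425 ms, SSRT mean 240 ms, and a
#' small choice-error rate; the dispersion parameters are calibrated so a
#' simulated cohort run through the full three-staircase task reproduces the
#' canonical behavioural profile (inhibition ~80% / ~47-49% / ~9% on the
#' short / medium / long staircases, SSRT estimate ~235 ms).
#'
#' @param go_rt_mu,go_rt_sigma,go_rt_tau ex-Gaussian parameters, ms.
#' @param ssrt_mean,ssrt_sd stop-process latency distribution, ms.
#' @param choice_error_rate probability of pressing the wrong button on a
#'   responded trial.
#' @return list of class `responder_model`.
#' @export
responder_model <- function(go_rt_mu = 375, go_rt_sigma = 90, go_rt_tau = 50,
                            ssrt_mean = 240, ssrt_sd = 50,
                            choice_error_rate = 0.02) {
  stopifnot(go_rt_sigma >= 0, go_rt_tau >= 0, ssrt_sd >= 0,
            choice_error_rate >= 0, choice_error_rate <= 1)
  structure(list(go_rt_mu = go_rt_mu, go_rt_sigma = go_rt_sigma,
                 go_rt_tau = go_rt_tau, ssrt_mean = ssrt_mean,
                 ssrt_sd = ssrt_sd, choice_error_rate = choice_error_rate),
            class = "responder_model")
}

#' Draw Go reaction times from the responder model
#'
#' Ex-Gaussian draws truncated below at 150 ms (implausibly fast responses
#' are floored, not redrawn, so the degenerate zero-dispersion model is
#' deterministic).
#'
#' @param model a `responder_model`.
#' @param n number of draws.
#' @return numeric vector of RTs in ms.
#' @export
sample_go_rt <- function(model, n = 1) {
  rt <- rnorm(n, model$go_rt_mu, model$go_rt_sigma) +
    if (model$go_rt_tau > 0) rexp(n, 1 / model$go_rt_tau) else 0
  pmax(rt, 150)
}

sample_ssrt <- function(model, n = 1) {
  pmax(rnorm(n, model$ssrt_mean, model$ssrt_sd), 50)
}

#' Race-model stop outcome
#'
#' Independent horse race: the response is inhibited iff the stop process
#' (launched at the stop-signal delay) finishes before the go process, i.e.
#' `ssd + ssrt < go_rt`.
#'
#' @param ssd_ms stop-signal delay, ms.
#' @param ssrt_ms stop-process latency, ms.
#' @param go_rt_ms go-process finishing time, ms.
#' @return logical: TRUE if stopping succeeded.
#' @export
race_outcome <- function(ssd_ms, ssrt_ms, go_rt_ms) {
  stopifnot(all(ssd_ms >= 0), all(ssrt_ms >= 0), all(go_rt_ms >= 0))
  ssd_ms + ssrt_ms < go_rt_ms
}

#' Simulate a participant's behaviour through a session schedule
#'
#' Executes the task rules online against the race-model responder: a pure-Go
#' pretest establishes the pretest Go RT; short/long SSDs then track 20%/80%
#' of the running 16-trial Go RT mean, and the medium staircase starts at 45%
#' of the pretest RT and steps 30 ms up/down after successful/failed stops
#' under the 50 ms separation constraint.
#'
#' @param schedule a `session_schedule` from [build_session_schedule()].
#' @param model a `responder_model`.
#' @param seed integer seed (substreamed; independent of the schedule seed).
#' @param pretest_n_trials pure-Go pretest length (default 32).
#' @return list of class `behavioral_record` with elements
#'   \describe{
#'     \item{trials}{per-trial data.frame: schedule columns plus realised
#'       `ssd_ms`, `responded`, `correct`, `go_rt_ms`, `stop_success`,
#'       `face`, `slow`.}
#'     \item{pretest_go_rt_ms}{mean pretest Go RT.}
#'     \item{summary}{median Go RT, mean medium SSD, SSRT estimate
#'       (median Go RT - mean medium SSD), and percent inhibition per
#'       staircase.}
#'   }
#' @export
simulate_behavior <- function(schedule, model = responder_model(), seed = 1,
                              pretest_n_trials = 32) {
  tr <- schedule$trials
  n <- nrow(tr)
  with_substream(seed, "behavior", {
    pretest <- sample_go_rt(model, pretest_n_trials)
    pretest_rt <- mean(pretest)
    medium <- medium_staircase_init(pretest_rt)

    go_hist <- numeric(0)
    ssd <- rep(NA_real_, n)
    responded <- logical(n); correct <- rep(NA, n)
    go_rt <- rep(NA_real_, n); stop_success <- rep(NA, n)
    face <- character(n); slow <- logical(n)
    # concurrent yoked SSDs and post-update medium value, recorded on medium
    # stop trials so the separation constraint is auditable
    short_ref <- rep(NA_real_, n); long_ref <- rep(NA_real_, n)
    medium_after <- rep(NA_real_, n)

    for (i in seq_len(n)) {
      grt <- sample_go_rt(model, 1)
      if (tr$kind[i] == "go") {
        responded[i] <- TRUE
        correct[i] <- runif(1) >= model$choice_error_rate
        go_rt[i] <- grt
        go_hist <- c(go_hist, grt)
        fb <- feedback("go", TRUE, correct[i], grt, pretest_rt)
      } else {
        sl <- short_long_ssd(go_hist, pretest_rt)
        ssd[i] <- switch(tr$staircase[i],
                         short = sl[["short_ms"]],
                         long = sl[["long_ms"]],
                         medium = medium)
        srt <- sample_ssrt(model, 1)
        stop_success[i] <- race_outcome(ssd[i], srt, grt)
        responded[i] <- !stop_success[i]
        if (responded[i]) go_rt[i] <- grt
        if (tr$staircase[i] == "medium") {
          medium <- update_medium_staircase(medium, stop_success[i],
                                            sl[["short_ms"]], sl[["long_ms"]])
          short_ref[i] <- sl[["short_ms"]]; long_ref[i] <- sl[["long_ms"]]
          medium_after[i] <- medium
        }
        fb <- feedback("stop", responded[i], go_rt_ms = grt,
                       pretest_go_rt_ms = pretest_rt)
      }
      face[i] <- fb$face; slow[i] <- fb$slow
    }

    tr$ssd_ms <- ssd
    tr$responded <- responded; tr$correct <- correct
    tr$go_rt_ms <- go_rt; tr$stop_success <- stop_success
    tr$face <- face; tr$slow <- slow
    tr$short_ref_ms <- short_ref; tr$long_ref_ms <- long_ref
    tr$medium_after_ms <- medium_after

    stop_tr <- tr[tr$kind == "stop", ]
    p_inhibit <- vapply(c("short", "medium", "long"), function(s)
      100 * mean(stop_tr$stop_success[stop_tr$staircase == s]), numeric(1))
    med_ssd <- mean(stop_tr$ssd_ms[stop_tr$staircase == "medium"])
    med_go <- median(tr$go_rt_ms[tr$kind == "go"], na.rm = TRUE)

    structure(list(
      trials = tr,
      pretest_go_rt_ms = pretest_rt,
      summary = list(median_go_rt_ms = med_go,
                     mean_medium_ssd_ms = med_ssd,
                     ssrt_ms = med_go - med_ssd,
                     p_inhibit_pct = p_inhibit)),
      class = "behavioral_record")
  })
}

#' @export
print.behavioral_record <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<behavioral_record> %d trials; median Go RT %.0f ms; ",
                     "SSRT %.0f ms\n  P(inhibit) short/medium/long: ",
                     "%.0f%% / %.0f%% / %.0f%%\n"),
              nrow(x$trials), s$median_go_rt_ms, s$ssrt_ms,
              s$p_inhibit_pct[1], s$p_inhibit_pct[2], s$p_inhibit_pct[3]))
  invisible(x)
}
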