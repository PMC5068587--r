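# Cohort simulation: balanced drug groups, questionnaire traits drawn from
# instrument-matched distributions, and per-participant sessions.

#' Cohort configuration
#'
#' @param groups named integer vector of group sizes.  The default mirrors a
#'   four-arm acute-dose design (placebo 8, buspirone 9, triazolam 9,
#'   pregabalin 8; n = 34).
#' @param drug_multipliers named amplitude multipliers per group (placebo 1;
#'   anxiolytic arms attenuate the conflict burst).
#' @param seed master seed; every participant derives independent substreams.
#' @param task list of [build_session_schedule()] arguments.
#' @param responder a `responder_model`.
#' @param eeg an `eeg_params`, or NULL for a behaviour-only cohort.
#' @param injection a `conflict_injection`.
#' @param traits list of trait distribution parameters: means/sds for
#'   neuroticism (EPQ-R, clipped to 0-24), trait anxiety (STAI-T, 20-80) and
#'   BIS (7-28).  Defaults match the cohort summary table
#'   (9 (6), 38 (8), 21 (8)).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(groups = c(placebo = 8, buspirone = 9,
                                     triazolam = 9, pregabalin = 8),
                          drug_multipliers = c(placebo = 1, buspirone = 0.3,
                                               triazolam = 0.3, pregabalin = 0.3),
                          seed = 1,
                          task = list(n_blocks = 3, trials_per_block = 128,
                                      stop_every = 4),
                          responder = responder_model(),
                          eeg = eeg_params(),
                          injection = conflict_injection(),
                          traits = list(neuroticism = c(mean = 9, sd = 6),
                                        trait_anxiety = c(mean = 38, sd = 8),
                                        bis = c(mean = 21, sd = 8))) {
  stopifnot(all(names(groups) %in% names(drug_multipliers)))
  structure(list(groups = groups, drug_multipliers = drug_multipliers,
                 seed = seed, task = task, responder = responder,
                 eeg = eeg, injection = injection, traits = traits),
            class = "cohort_config")
}

draw_traits <- function(cfg_traits, n) {
  clip_round <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)
  data.frame(
    neuroticism = clip_round(rnorm(n, cfg_traits$neuroticism["mean"],
                                   cfg_traits$neuroticism["sd"]), 0, 24),
    trait_anxiety = clip_round(rnorm(n, cfg_traits$trait_anxiety["mean"],
                                     cfg_traits$trait_anxiety["sd"]), 20, 80),
    bis = clip_round(rnorm(n, cfg_traits$bis["mean"],
                           cfg_traits$bis["sd"]), 7, 28))
}

#' Generate a simulated cohort
#'
#' Each participant gets a seeded schedule, a race-model behavioural session
#' and (unless `config$eeg` is NULL) a continuous EEG record with the conflict
#' burst scaled by the group's drug multiplier and, when `trait_coupling` is
#' nonzero, by `1 + trait_coupling * (neuroticism - mean)/sd` (floored at 0).
#'
#' @param config a `cohort_config`.
#' @return list of participant records, each a list with `id`, `group`,
#'   `traits` (one-row data.frame), `schedule`, `behavior` and `eeg`
#'   (NULL for behaviour-only cohorts).
#' @export
generate_cohort <- function(config = cohort_config()) {
  n <- sum(config$groups)
  group <- rep(names(config$groups), config$groups)
  traits <- with_substream(config$seed, "traits",
                           draw_traits(config$traits, n))
  tc <- config$traits$neuroticism
  lapply(seq_len(n), function(i) {
    pseed <- substream_seed(config$seed, sprintf("participant-%03d", i))
    sched <- do.call(build_session_schedule,
                     c(config$task, list(seed = pseed)))
    beh <- simulate_behavior(sched, config$responder, seed = pseed)
    rec <- list(id = sprintf("sub-%03d", i), group = group[i],
                traits = traits[i, , drop = FALSE],
                schedule = sched, behavior = beh, eeg = NULL)
    if (!is.null(config$eeg)) {
      z <- (traits$neuroticism[i] - tc["mean"]) / tc["sd"]
      gain <- max(0, 1 + config$injection$trait_coupling * z)
      inj <- config$injection
      inj$drug_multiplier <- config$drug_multipliers[[group[i]]]
      rec$eeg <- synthesize_eeg(beh, config$eeg, inj, seed = pseed,
                                gain = gain)
    }
    rec
  })
}
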