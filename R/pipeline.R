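# Orchestration: declarative run configuration, cohort simulation to disk,
# end-to-end analysis, and a run manifest with per-file checksums.

#' Default run configuration
#'
#' A fully serialisable description of one simulate-preprocess-extract-test
#' run.  All randomness flows from `seed` through named substreams, so an
#' identical config reproduces identical outputs.
#'
#' @param seed master seed.
#' @param ... overrides for any top-level field.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    groups = list(placebo = 8, buspirone = 9, triazolam = 9, pregabalin = 8),
    drug_multipliers = list(placebo = 1, buspirone = 0.3,
                            triazolam = 0.3, pregabalin = 0.3),
    task = list(n_blocks = 3, trials_per_block = 128, stop_every = 4),
    responder = list(go_rt_mu = 375, go_rt_sigma = 90, go_rt_tau = 50,
                     ssrt_mean = 240, ssrt_sd = 50, choice_error_rate = 0.02),
    eeg = list(pink_noise_scale = 10, mains_hz = 50, mains_amp = 2,
               blink_rate = 15, blink_amp_fp1 = 150),
    injection = list(amplitude = 5, band = c(4, 12), target_channel = "F8",
                     block_profile = c(1, 0, 1), trait_coupling = 0),
    preprocessing = list(blink_threshold_uv = 75,
                         artifact_threshold_uv = 150, artifact_pad_s = 0.1),
    analysis = list(channels = c("F7", "F3", "Fz", "F4", "F8"),
                    focus_channel = "F8", blocks = c(1, 3),
                    freq_orders = c("linear", "quadratic", "cubic"),
                    p_enter = 0.05))
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

config_to_cohort <- function(cfg) {
  cohort_config(
    groups = unlist(cfg$groups),
    drug_multipliers = unlist(cfg$drug_multipliers),
    seed = cfg$seed,
    task = cfg$task,
    responder = do.call(responder_model, cfg$responder),
    eeg = do.call(eeg_params, cfg$eeg),
    injection = do.call(conflict_injection,
                        cfg$injection[setdiff(names(cfg$injection),
                                              "drug_multiplier")]))
}

#' Simulate a cohort and write it to disk
#'
#' One EDF + events TSV + behaviour CSV per participant, a cohort traits CSV,
#' and a manifest (config snapshot, package version, md5 checksum per file).
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if needed).
#' @return the in-memory cohort, invisibly.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config_to_cohort(cfg))
  files <- character(0)
  for (p in cohort) {
    base <- file.path(out_dir, p$id)
    write_eeg_edf(p$eeg, paste0(base, "_eeg.edf"))
    write_events_tsv(p$eeg$events, paste0(base, "_events.tsv"))
    write.csv(p$behavior$trials, paste0(base, "_behavior.csv"),
              row.names = FALSE)
    files <- c(files, paste0(base, c("_eeg.edf", "_events.tsv",
                                     "_behavior.csv")))
  }
  traits <- do.call(rbind, lapply(cohort, function(p)
    cbind(participant = p$id, group = p$group, p$traits)))
  tf <- file.path(out_dir, "traits.csv")
  write.csv(traits, tf, row.names = FALSE)
  files <- c(files, tf)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(
                     utils::packageVersion("gcsr")),
                   files = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(cohort)
}

#' Analyse a simulated (or loaded) cohort
#'
#' Runs preprocessing and GCSR extraction per participant, then the
#' contrast-based statistics: per-block one-sample conflict-contrast tests at
#' the focus channel, the drug-group one-way ANOVA on the composite contrast
#' score, per-frequency trait correlations, a forward stepwise regression of
#' each trait on the 9 focus-channel GCSR frequencies (block 1), and a
#' descriptive per-channel GCSR gradient.
#'
#' @param cohort list of participant records from [generate_cohort()].
#' @param cfg a `run_config` (analysis and preprocessing options).
#' @return list of class `gcsr_results`: `gcsr` (long table), `cells`,
#'   `scores`, `tests`, `group_tests`, `correlations`, `stepwise`,
#'   `channel_gradient`, `report` (character lines).
#' @export
analyze_cohort <- function(cohort, cfg = default_run_config()) {
  an <- cfg$analysis
  pp <- cfg$preprocessing
  per <- lapply(cohort, function(p) {
    eeg <- preprocess_eeg(p$eeg, pp$blink_threshold_uv,
                          pp$artifact_threshold_uv, pp$artifact_pad_s)
    ex <- extract_gcsr(eeg, channels = an$channels, preprocess = FALSE)
    list(id = p$id, group = p$group, traits = p$traits, ex = ex)
  })
  cells <- do.call(rbind, lapply(per, function(x)
    cbind(participant = x$id, x$ex$cells)))
  gcsr <- do.call(rbind, lapply(per, function(x)
    cbind(participant = x$id, x$ex$gcsr)))
  groups <- setNames(vapply(per, `[[`, "", "group"),
                     vapply(per, `[[`, "", "id"))
  traits <- do.call(rbind, lapply(per, function(x)
    cbind(participant = x$id, x$traits)))

  # composite contrast scores per frequency order at the focus channel
  focus_cells <- cells[cells$channel == an$focus_channel, ]
  scores <- do.call(rbind, lapply(an$freq_orders, function(ord)
    cbind(freq_order = ord, contrast_score(focus_cells, ord))))

  tests <- list(); group_tests <- list()
  for (ord in an$freq_orders) for (b in an$blocks) {
    sc <- scores[scores$freq_order == ord & scores$block == b, ]
    lab <- sprintf("Stop-Go x SSD(quad) x freq(%s), %s block %d",
                   ord, an$focus_channel, b)
    tests[[lab]] <- one_sample_contrast_test(sc$score, lab)
    if (length(unique(groups)) > 1) {
      group_tests[[paste(lab, "x group")]] <-
        group_contrast_anova(sc$score, groups[sc$participant],
                             paste(lab, "x group"))
    }
  }

  g8 <- gcsr[gcsr$channel == an$focus_channel,
             c("participant", "block", "freq_hz", "gcsr")]
  correlations <- do.call(rbind, lapply(
    intersect(c("neuroticism", "trait_anxiety", "bis"), names(traits)),
    function(tr) trait_correlations(g8, traits, tr)))

  # stepwise: block-1 GCSR at the 9 frequencies predicting each trait
  stepwise <- lapply(
    setNames(nm = intersect(c("neuroticism", "trait_anxiety", "bis"),
                            names(traits))),
    function(tr) {
      b1 <- g8[g8$block == min(an$blocks), ]
      X <- do.call(cbind, lapply(split(b1, b1$freq_hz), function(d)
        d$gcsr[order(d$participant)]))
      colnames(X) <- paste0("gcsr_", sort(unique(b1$freq_hz)), "Hz")
      y <- traits[[tr]][order(traits$participant)]
      stepwise_forward(X, y, an$p_enter)
    })

  # per-channel descriptive gradient (focus channel vs the rest)
  gsel <- gcsr[gcsr$block %in% an$blocks, ]
  ch_means <- tapply(gsel$gcsr, gsel$channel, mean, na.rm = TRUE)
  gradient <- list(channel_means = ch_means,
                   focus_minus_others = unname(
                     ch_means[an$focus_channel] -
                       mean(ch_means[setdiff(names(ch_means),
                                             an$focus_channel)])))

  report <- c(
    sprintf("participants analysed: %d", length(per)),
    sprintf("epochs per participant: %d stop trials x 2",
            sum(cohort[[1]]$behavior$trials$kind == "stop")),
    vapply(tests, function(t)
      sprintf("%s: F(%d,%d)=%.3f p=%.4g", t$effect, t$df1, t$df2, t$F, t$p),
      ""),
    vapply(group_tests, function(t)
      sprintf("%s: F(%d,%d)=%.3f p=%.4g", t$effect, t$df1, t$df2, t$F, t$p),
      ""),
    sprintf("channel gradient (%s - others): %.4f",
            an$focus_channel, gradient$focus_minus_others))

  structure(list(gcsr = gcsr, cells = cells, scores = scores, tests = tests,
                 group_tests = group_tests, correlations = correlations,
                 stepwise = stepwise, channel_gradient = gradient,
                 traits = traits, groups = groups, report = report),
            class = "gcsr_results")
}

#' @export
print.gcsr_results <- function(x, ...) {
  cat("<gcsr_results>\n")
  cat(paste0("  ", x$report, "\n"), sep = "")
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' simulate -> preprocess -> extract -> test.  With `out_dir`, the cohort
#' files, tidy result CSVs (GCSR spectra, contrast scores, test table,
#' correlations) and a human-readable report are written to disk.
#'
#' @param cfg a `run_config`.
#' @param out_dir optional output directory.
#' @return a `gcsr_results` object.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir = NULL) {
  cohort <- if (is.null(out_dir)) generate_cohort(config_to_cohort(cfg))
            else cmd_simulate(cfg, out_dir)
  res <- analyze_cohort(cohort, cfg)
  if (!is.null(out_dir)) {
    write.csv(res$gcsr, file.path(out_dir, "gcsr_spectra.csv"),
              row.names = FALSE)
    write.csv(res$scores, file.path(out_dir, "contrast_scores.csv"),
              row.names = FALSE)
    test_tab <- do.call(rbind, lapply(c(res$tests, res$group_tests),
                                      function(t)
      data.frame(effect = t$effect, F = t$F, df1 = t$df1, df2 = t$df2,
                 p = t$p)))
    write.csv(test_tab, file.path(out_dir, "tests.csv"), row.names = FALSE)
    write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
    writeLines(res$report, file.path(out_dir, "report.txt"))
  }
  res
}
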