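# Modified stop-signal task: schedule construction, staircase state machines
# and feedback rules.  Three nominal staircases deliver short, medium and long
# stop-signal delays (SSDs): short/long are yoked to 20% / 80% of the running
# mean Go reaction time, while the medium staircase tracks the ~50% stopping
# point in 30 ms steps under a 50 ms separation constraint.

#' Build a stop-signal session schedule
#'
#' Lays out the trial sequence for a session: `n_blocks` blocks of
#' `trials_per_block` trials, with exactly one stop trial in every consecutive
#' (disjoint) window of `stop_every` trials, at a seeded random position
#' within the window.  Arrow directions are balanced left/right within each
#' block, and the three staircase labels are cycled over the stop trials so
#' that their counts differ by at most one within a block and are equal over
#' a standard 3 x 128 session.
#'
#' @param n_blocks number of blocks (default 3).
#' @param trials_per_block trials per block (default 128); must be divisible
#'   by `stop_every`.
#' @param stop_every stop-trial rate: one stop per this many trials (default 4).
#' @param seed integer seed controlling stop positions, arrows and staircase
#'   label order.
#' @return An object of class `session_schedule`: a list with `trials` (a
#'   data.frame with columns `index`, `block`, `kind`, `arrow`, `staircase`,
#'   `ssd_ms`), `pretest_go_rt_ms` (NA until a pretest is run) and `seed`.
#'   `ssd_ms` is NA at build time; delays are realised online during
#'   simulation or testing.
#' @export
build_session_schedule <- function(n_blocks = 3, trials_per_block = 128,
                                   stop_every = 4, seed = 1) {
  if (!is_count(n_blocks) || n_blocks < 1)
    stop_config("n_blocks must be a positive integer")
  if (!is_count(trials_per_block) || trials_per_block %% stop_every != 0)
    stop_config("trials_per_block (%s) must be divisible by stop_every (%s)",
                trials_per_block, stop_every)

  n_windows <- trials_per_block %/% stop_every
  trials <- with_substream(seed, "schedule", {
    # One base permutation of the staircase labels; each block uses a rotation
    # so that over three blocks every label takes the short straw equally often.
    labels <- c("short", "medium", "long")
    base_perm <- sample(labels)
    blocks <- lapply(seq_len(n_blocks), function(b) {
      kind <- rep("go", trials_per_block)
      # one stop trial per disjoint window of stop_every trials
      pos <- (seq_len(n_windows) - 1L) * stop_every +
        sample.int(stop_every, n_windows, replace = TRUE)
      kind[pos] <- "stop"
      # balanced arrows within block
      arrow <- sample(rep(c("left", "right"), length.out = trials_per_block))
      perm <- base_perm[((seq_along(base_perm) + b - 2L) %% 3L) + 1L]
      staircase <- rep(NA_character_, trials_per_block)
      staircase[pos] <- rep(perm, length.out = n_windows)
      data.frame(block = b, kind = kind, arrow = arrow,
                 staircase = staircase, stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
  trials <- cbind(index = seq_len(nrow(trials)), trials)
  trials$ssd_ms <- NA_real_
  structure(list(trials = trials, pretest_go_rt_ms = NA_real_, seed = seed),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  tab <- table(x$trials$block, x$trials$kind)
  cat(sprintf("<session_schedule> %d trials in %d block(s); seed %s\n",
              nrow(x$trials), length(unique(x$trials$block)),
              format(x$seed)))
  print(tab)
  invisible(x)
}

#' Short and long SSDs from recent Go reaction times
#'
#' The short and long stop-signal delays are yoked to 20% and 80% of the mean
#' Go reaction time over the previous 16 Go trials.  When fewer than 16 Go
#' RTs have accrued, the mean of all available RTs is used; with none, the
#' pretest Go RT stands in.
#'
#' @param recent_go_rts_ms numeric vector of recent Go RTs (ms), most recent
#'   last; at most the last 16 are used.
#' @param pretest_go_rt_ms fallback Go RT (ms) when no Go trials have accrued.
#' @return named numeric vector `c(short_ms, long_ms)` (continuous ms; rounding
#'   to the sample grid happens when delays are realised as event times).
#' @export
short_long_ssd <- function(recent_go_rts_ms, pretest_go_rt_ms = NULL) {
  if (length(recent_go_rts_ms) == 0) {
    if (is.null(pretest_go_rt_ms) || is.na(pretest_go_rt_ms))
      stop_config("no Go RTs available and no pretest Go RT to fall back on")
    m <- pretest_go_rt_ms
  } else {
    if (any(recent_go_rts_ms < 0)) stop_config("negative Go RT")
    m <- mean(tail(recent_go_rts_ms, 16L))
  }
  c(short_ms = 0.20 * m, long_ms = 0.80 * m)
}

#' Starting SSD for the medium (tracking) staircase
#'
#' The medium staircase starts at 45% of the pre-training Go reaction time.
#'
#' @param pretest_go_rt_ms mean Go RT (ms) from the pure-Go pretest; must be
#'   positive.
#' @return starting SSD in ms.
#' @export
medium_staircase_init <- function(pretest_go_rt_ms) {
  if (!is.numeric(pretest_go_rt_ms) || length(pretest_go_rt_ms) != 1 ||
      is.na(pretest_go_rt_ms) || pretest_go_rt_ms <= 0)
    stop_config("pretest Go RT must be a positive number")
  0.45 * pretest_go_rt_ms
}

#' Update the medium staircase after a stop trial
#'
#' The medium SSD increases by 30 ms after successful stopping and decreases
#' by 30 ms after failed stopping, under the restriction that it may never
#' come within 50 ms of the concurrent short or long SSD.  A proposed value
#' inside a forbidden zone is moved to the zone edge on the side of the
#' conflicting staircase where the proposal lies; the result is floored at 0.
#'
#' @param current_ssd_ms current medium SSD (ms).
#' @param stop_success logical: did the participant withhold the response?
#' @param short_ms,long_ms concurrent short and long SSDs (ms).
#' @param step_ms staircase step (default 30 ms).
#' @param min_gap_ms separation constraint (default 50 ms).
#' @return updated medium SSD in ms.
#' @export
update_medium_staircase <- function(current_ssd_ms, stop_success,
                                    short_ms, long_ms,
                                    step_ms = 30, min_gap_ms = 50) {
  if (short_ms > long_ms)
    stop_config("schedule inconsistency: short SSD (%.1f) > long SSD (%.1f)",
                short_ms, long_ms)
  p <- current_ssd_ms + if (isTRUE(stop_success)) step_ms else -step_ms
  for (i in 1:4) {  # zones can chain when short and long are close
    moved <- FALSE
    for (conflict in c(short_ms, long_ms)) {
      if (abs(p - conflict) < min_gap_ms) {
        p <- if (p >= conflict) conflict + min_gap_ms else conflict - min_gap_ms
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  max(p, 0)
}

#' Trial feedback (smiley/frowney and slow flag)
#'
#' Stop trials earn a smiley iff the response was withheld.  Go trials earn a
#' smiley iff a response was made on the correct side.  A "slow" flag is
#' raised on responded Go trials whose RT strictly exceeds 1.5 times the
#' pretest Go RT, to discourage strategic slowing.
#'
#' @param kind "go" or "stop".
#' @param responded logical; was any response made?
#' @param correct_button logical; was the response on the correct side
#'   (ignored if no response)?
#' @param go_rt_ms response time (ms); required iff `responded`.
#' @param pretest_go_rt_ms pretest Go RT (ms).
#' @return list with `face` ("smiley"/"frowney") and `slow` (logical).
#' @export
feedback <- function(kind, responded, correct_button = NA,
                     go_rt_ms = NA, pretest_go_rt_ms = NA) {
  stopifnot(kind %in% c("go", "stop"))
  if (responded && is.na(go_rt_ms))
    stop_config("go_rt_ms required when responded")
  face <- if (kind == "stop") {
    if (!responded) "smiley" else "frowney"
  } else {
    if (responded && isTRUE(correct_button)) "smiley" else "frowney"
  }
  slow <- kind == "go" && responded && !is.na(pretest_go_rt_ms) &&
    go_rt_ms > 1.5 * pretest_go_rt_ms
  list(face = face, slow = slow)
}

#' Write / read a schedule as a tab-separated trial table
#'
#' Columns: index, block, kind, arrow, staircase, ssd_ms, onset_s.  Onsets are
#' filled from a realised behavioural record when available, otherwise NA.
#'
#' @param schedule a `session_schedule`.
#' @param path file path for the TSV.
#' @param onsets_s optional per-trial onset times in seconds.
#' @return `path`, invisibly (writer); a `session_schedule` (reader).
#' @export
write_schedule_tsv <- function(schedule, path, onsets_s = NULL) {
  tr <- schedule$trials
  tr$onset_s <- if (is.null(onsets_s)) NA_real_ else onsets_s
  write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  tr$staircase[tr$staircase == ""] <- NA_character_
  sched <- structure(list(trials = tr[setdiff(names(tr), "onset_s")],
                          pretest_go_rt_ms = NA_real_, seed = NA),
                     class = "session_schedule")
  sched
}
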