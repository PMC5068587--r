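# Contrast-based inference: orthogonal polynomial weights, the composite
# Stop-Go x SSD-quadratic x frequency-polynomial contrast score, single-df
# within-subject and between-group tests, per-frequency trait correlations,
# and forward stepwise regression.

#' Orthogonal polynomial contrast weights
#'
#' Standard integer-valued orthogonal polynomial weights for equally spaced
#' levels (e.g. 3 levels: linear (-1, 0, 1), quadratic (1, -2, 1)).  Computed
#' from the orthonormal polynomial basis and rescaled to the smallest integer
#' form; weight vectors of different order on the same levels are mutually
#' orthogonal and sum to zero.
#'
#' @param n_levels number of levels (>= 2).
#' @param order "linear", "quadratic" or "cubic" (or the degree as integer).
#' @return numeric weight vector of length `n_levels`.
#' @export
poly_weights <- function(n_levels, order) {
  deg <- if (is.character(order)) {
    match(match.arg(order, c("linear", "quadratic", "cubic")),
          c("linear", "quadratic", "cubic"))
  } else as.integer(order)
  if (deg >= n_levels)
    stop_config("contrast order (%d) must be below n_levels (%d)",
                deg, n_levels)
  w <- stats::contr.poly(n_levels)[, deg]
  u <- w / min(abs(w[abs(w) > 1e-12]))
  for (m in 1:720) {
    if (all(abs(u * m - round(u * m)) < 1e-8)) return(round(u * m))
  }
  u  # scale is immaterial for the test statistics
}

# Fixed within-subject weights: Stop vs Go, and the SSD quadratic in the
# sign convention where positive = conflict-specific (medium) excess.
W_STOPGO <- c(stop = 1, go = -1)
W_SSD_QUAD <- c(short = -0.5, medium = 1, long = -0.5)

#' Composite conflict contrast score
#'
#' Per participant, block and channel, the single-df composite
#' Stop-Go x SSD-quadratic x frequency-polynomial score:
#' `sum over cells of mean_log_power * w_type * w_ssd * w_freq(order)`.
#' The Stop-Go weights are (+1, -1) and the SSD quadratic uses
#' (-1/2, 1, -1/2) so one unit equals one log-power unit of conflict excess
#' (the textbook (1, -2, 1) version differs only by a factor of -2, which the
#' F statistic ignores).  Participants/blocks with an incomplete 2 x 3 x 9
#' cell structure get an NA score.
#'
#' @param cells cell table from [average_cells()], optionally with a
#'   `participant` column.
#' @param freq_order polynomial order for the frequency factor
#'   ("linear", "quadratic" or "cubic"; 4..12 Hz as successive levels).
#' @return data.frame with grouping keys (`participant`, `block`, `channel`)
#'   and `score`.
#' @export
contrast_score <- function(cells, freq_order = "cubic") {
  wf <- poly_weights(length(GCSR_FREQS), freq_order)
  names(wf) <- GCSR_FREQS
  keys <- intersect(c("participant", "block", "channel"), names(cells))
  cells$w <- W_STOPGO[cells$trial_type] *
    W_SSD_QUAD[cells$ssd_level] *
    wf[as.character(cells$freq_hz)]
  groups <- cells[keys]
  split_idx <- split(seq_len(nrow(cells)), groups, drop = TRUE)
  res <- lapply(split_idx, function(idx) {
    d <- cells[idx, ]
    sc <- if (nrow(d) < 54 || anyNA(d$mean_log_power)) NA_real_
          else sum(d$mean_log_power * d$w)
    cbind(d[1, keys, drop = FALSE], score = sc)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' One-sample test of a within-subject contrast
#'
#' Tests whether the mean contrast score across participants differs from
#' zero: `t = mean / (sd / sqrt(n))`, reported as `F = t^2` with df (1, n-1)
#' and a two-sided uncorrected p-value.
#'
#' @param scores numeric vector of per-participant contrast scores.
#' @param effect label for the report.
#' @return list of class `gcsr_test`: `effect`, `F`, `df1`, `df2`, `p`,
#'   `direction` (sign of the mean), `degenerate` (zero variance flag).
#' @export
one_sample_contrast_test <- function(scores, effect = "contrast") {
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 2) stop_config("need at least 2 scores")
  s <- sd(scores)
  if (s == 0) {
    return(structure(list(effect = effect, F = NA_real_, df1 = 1, df2 = n - 1,
                          p = NA_real_, direction = sign(mean(scores)),
                          degenerate = TRUE), class = "gcsr_test"))
  }
  t_stat <- mean(scores) / (s / sqrt(n))
  structure(list(effect = effect, F = t_stat^2, df1 = 1, df2 = n - 1,
                 p = 2 * pt(-abs(t_stat), n - 1),
                 direction = sign(mean(scores)), degenerate = FALSE),
            class = "gcsr_test")
}

#' One-way ANOVA of contrast scores across groups
#'
#' Between-group test on the per-participant composite contrast scores
#' (e.g. drug group differences in conflict rhythmicity), with
#' df (k - 1, N - k) and an uncorrected p-value.
#'
#' @param scores numeric per-participant scores.
#' @param group group labels (factor or character), >= 2 groups, each n >= 2.
#' @param effect label for the report.
#' @return `gcsr_test` list, plus `group_means`.
#' @export
group_contrast_anova <- function(scores, group, effect = "group") {
  ok <- !is.na(scores) & !is.na(group)
  scores <- scores[ok]; group <- factor(group[ok])
  if (nlevels(group) < 2) stop_config("need at least 2 groups")
  if (any(table(group) < 2)) stop_config("every group needs n >= 2")
  fit <- anova(lm(scores ~ group))
  structure(list(effect = effect, F = fit$`F value`[1],
                 df1 = fit$Df[1], df2 = fit$Df[2],
                 p = fit$`Pr(>F)`[1],
                 direction = NA_real_, degenerate = FALSE,
                 group_means = tapply(scores, group, mean)),
            class = "gcsr_test")
}

#' @export
print.gcsr_test <- function(x, ...) {
  cat(sprintf("%s: F(%d,%d) = %.3f, p = %.4g%s\n", x$effect, x$df1, x$df2,
              x$F, x$p, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Per-frequency correlations between GCSR and a trait
#'
#' Pearson correlations, per block and frequency bin, between participants'
#' GCSR values and a questionnaire trait score; two-sided uncorrected
#' p-values.
#'
#' @param gcsr_table data.frame with columns `participant`, `block`,
#'   `freq_hz`, `gcsr` (typically the F8 slice of [gcsr_spectrum()] output).
#' @param trait_scores data.frame with `participant` and one column named in
#'   `trait`.
#' @param trait trait column name.
#' @return data.frame: `block`, `freq_hz`, `trait`, `n`, `r`, `p`.
#' @export
trait_correlations <- function(gcsr_table, trait_scores, trait) {
  d <- merge(gcsr_table, trait_scores[, c("participant", trait)],
             by = "participant")
  combos <- unique(d[, c("block", "freq_hz")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    s <- d[d$block == combos$block[i] & d$freq_hz == combos$freq_hz[i], ]
    s <- s[complete.cases(s[, c("gcsr", trait)]), ]
    n <- nrow(s)
    if (n < 3 || sd(s$gcsr) == 0 || sd(s[[trait]]) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(s$gcsr, s[[trait]])
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(block = combos$block[i], freq_hz = combos$freq_hz[i],
               trait = trait, n = n, r = r, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$block, out$freq_hz), ]
}

#' Forward stepwise regression with an F-to-enter criterion
#'
#' Classical forward selection: at each step, the candidate predictor with
#' the largest change-in-F (nested-model F on 1 and n - k - 1 df) enters if
#' its p-value is below `p_enter`; there is no removal step.  Reported per
#' entry: the multiple correlation `r` of the grown model, `F_change`, its
#' df pair and p-value.
#'
#' @param predictors numeric matrix or data.frame (n x p), columns named.
#' @param response numeric vector.
#' @param p_enter entry threshold (default 0.05, uncorrected).
#' @return list: `selected` (names in entry order; possibly empty) and
#'   `steps` (data.frame: `predictor`, `r`, `F_change`, `df1`, `df2`, `p`).
#' @export
stepwise_forward <- function(predictors, response, p_enter = 0.05) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- complete.cases(X) & !is.na(response)
  X <- X[ok, , drop = FALSE]; y <- response[ok]
  n <- length(y)
  selected <- character(0)
  steps <- data.frame(predictor = character(0), r = numeric(0),
                      F_change = numeric(0), df1 = integer(0),
                      df2 = integer(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  rss <- function(cols) {
    if (length(cols) == 0) sum((y - mean(y))^2)
    else sum(lm.fit(cbind(1, X[, cols, drop = FALSE]), y)$residuals^2)
  }
  repeat {
    cand <- setdiff(colnames(X), selected)
    if (length(cand) == 0) break
    rss0 <- rss(selected)
    k <- length(selected) + 1L
    df2 <- n - k - 1L
    if (df2 < 1) break
    f_ch <- vapply(cand, function(v) {
      rss1 <- rss(c(selected, v))
      (rss0 - rss1) / (rss1 / df2)
    }, numeric(1))
    best <- names(which.max(f_ch))
    p <- pf(f_ch[best], 1, df2, lower.tail = FALSE)
    if (p >= p_enter) break
    selected <- c(selected, best)
    r2 <- 1 - rss(selected) / sum((y - mean(y))^2)
    steps <- rbind(steps, data.frame(
      predictor = best, r = sqrt(r2), F_change = unname(f_ch[best]),
      df1 = 1L, df2 = df2, p = unname(p), stringsAsFactors = FALSE))
  }
  list(selected = selected, steps = steps)
}

#' Simulate null cohorts of composite contrast scores
#'
#' Vectorised Monte-Carlo generator for calibrating the one-sample contrast
#' test: each participant's 2 x 3 (trial type x SSD level) cells are built
#' from independent white-noise epochs through the same Hanning/FFT log-power
#' path as the real pipeline (matrix form), and the composite
#' Stop-Go x SSD-quadratic x frequency contrast score is formed.  With no
#' injected rhythmicity the scores are exchangeable noise, so the test's
#' rejection rate at a given alpha estimates its type-I error.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_participants participants per cohort.
#' @param seed integer seed.
#' @param freq_order frequency-contrast order.
#' @param epochs_per_cell independent epochs averaged per cell (1 keeps the
#'   simulation cheap; more epochs only shrink cell noise).
#' @param batch cohorts per vectorised batch (memory knob).
#' @return list: `p_values` (length `n_cohorts`), `type1_at_05`
#'   (rejection rate at alpha = 0.05).
#' @export
simulate_null_contrast_scores <- function(n_cohorts, n_participants = 34,
                                          seed = 1, freq_order = "cubic",
                                          epochs_per_cell = 1, batch = 200) {
  wf <- poly_weights(length(GCSR_FREQS), freq_order)
  cell_grid <- expand.grid(trial_type = c("stop", "go"),
                           ssd_level = c("short", "medium", "long"),
                           stringsAsFactors = FALSE)
  wc <- W_STOPGO[cell_grid$trial_type] * W_SSD_QUAD[cell_grid$ssd_level]
  n_cells <- nrow(cell_grid)
  p_values <- numeric(n_cohorts)
  with_substream(seed, "null-cohorts", {
    done <- 0L
    while (done < n_cohorts) {
      b <- min(batch, n_cohorts - done)
      n_ep <- b * n_participants * n_cells * epochs_per_cell
      E <- matrix(rnorm(FS_HZ * n_ep), FS_HZ, n_ep)
      L <- hann_log_power_matrix(E)          # 9 x n_ep
      cell_vals <- crossprod(L, wf)          # per-epoch frequency contrast
      if (epochs_per_cell > 1) {
        cell_vals <- colMeans(matrix(cell_vals, epochs_per_cell))
      }
      cells <- matrix(cell_vals, n_cells)    # cells x (participants*b)
      scores <- matrix(crossprod(cells, wc), n_participants, b)
      m <- colMeans(scores)
      s <- apply(scores, 2, sd)
      t_stat <- m / (s / sqrt(n_participants))
      p_values[done + seq_len(b)] <-
        2 * pt(-abs(t_stat), n_participants - 1)
      done <- done + b
    }
  })
  list(p_values = p_values, type1_at_05 = mean(p_values < 0.05))
}
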