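test_that("polynomial contrast weights match the textbook integer tables", {
  expect_equal(poly_weights(3, "linear"), c(-1, 0, 1))
  expect_equal(poly_weights(3, "quadratic"), c(1, -2, 1))
  expect_equal(poly_weights(4, "linear"), c(-3, -1, 1, 3))
  expect_equal(poly_weights(4, "quadratic"), c(1, -1, -1, 1))
  expect_equal(poly_weights(4, "cubic"), c(-1, 3, -3, 1))
  # nine frequency levels (4..12 Hz)
  expect_equal(poly_weights(9, "linear"), -4:4)
  expect_equal(poly_weights(9, "quadratic"),
               c(28, 7, -8, -17, -20, -17, -8, 7, 28))
  expect_equal(poly_weights(9, "cubic"),
               c(-14, 7, 13, 9, 0, -9, -13, -7, 14))
  # zero sum and mutual orthogonality
  for (o1 in c("linear", "quadratic", "cubic")) {
    expect_equal(sum(poly_weights(9, o1)), 0)
    for (o2 in setdiff(c("linear", "quadratic", "cubic"), o1))
      expect_equal(sum(poly_weights(9, o1) * poly_weights(9, o2)), 0)
  }
  expect_error(poly_weights(3, "cubic"), "below n_levels")
})

test_that("the composite contrast score matches a brute-force triple sum", {
  base <- random_cells(20)
  flat <- base; flat$mean_log_power <- 1.7
  expect_equal(contrast_score(flat)$score, 0)
  # hardcoded weights, summed the slow way
  wf <- c(-14, 7, 13, 9, 0, -9, -13, -7, 14); names(wf) <- 4:12
  wt <- c(stop = 1, go = -1)
  ws <- c(short = -0.5, medium = 1, long = -0.5)
  brute <- 0
  for (i in seq_len(nrow(base))) {
    brute <- brute + base$mean_log_power[i] * wt[[base$trial_type[i]]] *
      ws[[base$ssd_level[i]]] * wf[[as.character(base$freq_hz[i])]]
  }
  expect_equal(contrast_score(base)$score, brute)
  # self-contrast: power equal to the weight gives sum of squared weights
  self <- base
  self$mean_log_power <- wt[self$trial_type] * ws[self$ssd_level] *
    wf[as.character(self$freq_hz)]
  expect_equal(contrast_score(self)$score,
               sum(self$mean_log_power^2))
})

test_that("incomplete or missing cells yield NA contrast scores", {
  base <- random_cells(21)
  holed <- base; holed$mean_log_power[5] <- NA
  expect_true(is.na(contrast_score(holed)$score))
  expect_true(is.na(contrast_score(base[-3, ])$score))
  # two participants, one broken: only that score is NA, order preserved
  two <- rbind(random_cells(22, participant = "sub-001"),
               random_cells(23, participant = "sub-002"))
  two$mean_log_power[two$participant == "sub-002"][1] <- NA
  sc <- contrast_score(two)
  expect_equal(sc$participant, c("sub-001", "sub-002"))
  expect_false(is.na(sc$score[1]))
  expect_true(is.na(sc$score[2]))
})

test_that("the one-sample contrast test is t-squared against t.test", {
  set.seed(30)
  x <- rnorm(24, mean = 0.4)
  got <- one_sample_contrast_test(x)
  tt <- t.test(x, mu = 0)
  expect_equal(got$F, unname(tt$statistic)^2)
  expect_equal(got$p, tt$p.value)
  expect_equal(got$df1, 1)
  expect_equal(got$df2, 23)
  expect_equal(got$direction, sign(mean(x)))
  # degenerate: zero variance
  deg <- one_sample_contrast_test(rep(2, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(one_sample_contrast_test(3), "at least 2")
})

test_that("the group ANOVA matches hand-computed sums of squares", {
  set.seed(31)
  g <- rep(c("a", "b", "c"), times = c(8, 9, 7))
  y <- rnorm(24) + c(a = 0, b = 0.5, c = 1)[g]
  got <- group_contrast_anova(y, g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 21)
  expect_equal(got$F, f_hand)
  expect_equal(got$df1, 2)
  expect_equal(got$df2, 21)
  expect_equal(got$p, pf(f_hand, 2, 21, lower.tail = FALSE))
  expect_equal(unname(got$group_means), unname(tapply(y, factor(g), mean)))
  # widely separated groups are detected
  strong <- group_contrast_anova(c(rnorm(10), rnorm(10, 10)),
                                 rep(c("a", "b"), each = 10))
  expect_lt(strong$p, 1e-6)
  expect_error(group_contrast_anova(rnorm(5), rep("a", 5)), "2 groups")
  expect_error(group_contrast_anova(rnorm(3), c("a", "a", "b")), "n >= 2")
})

test_that("trait correlations reproduce cor.test per block and frequency", {
  set.seed(32)
  participants <- sprintf("sub-%03d", 1:20)
  tab <- expand.grid(participant = participants, block = c(1, 3),
                     freq_hz = 4:12, stringsAsFactors = FALSE)
  tab$gcsr <- rnorm(nrow(tab))
  traits <- data.frame(participant = participants,
                       neuroticism = rnorm(20, 9, 4))
  got <- trait_correlations(tab, traits, "neuroticism")
  expect_equal(nrow(got), 2 * 9)
  sel <- tab$block == 3 & tab$freq_hz == 7
  ct <- cor.test(tab$gcsr[sel][match(participants, tab$participant[sel])],
                 traits$neuroticism)
  row <- got[got$block == 3 & got$freq_hz == 7, ]
  expect_equal(row$r, unname(ct$estimate))
  expect_equal(row$p, ct$p.value)
  expect_equal(row$n, 20)
  # perfect coupling: gcsr equal to the trait gives r = 1 everywhere
  coupled <- tab
  coupled$gcsr <- traits$neuroticism[match(coupled$participant,
                                           traits$participant)]
  expect_equal(trait_correlations(coupled, traits, "neuroticism")$r,
               rep(1, 18))
})

test_that("forward stepwise selection agrees with nested-model anova", {
  set.seed(33)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("signal", "n1", "n2", "n3")))
  y <- 2 * X[, "signal"] + rnorm(n, sd = 0.8)
  got <- stepwise_forward(X, y)
  expect_equal(got$selected[1], "signal")
  # step-1 F-to-enter equals the single-predictor regression F
  f1 <- unname(summary(lm(y ~ X[, "signal"]))$fstatistic["value"])
  expect_equal(got$steps$F_change[1], f1)
  expect_equal(got$steps$df2[1], n - 2)
  # multiple correlation of the grown model
  expect_equal(got$steps$r[1],
               sqrt(summary(lm(y ~ X[, "signal"]))$r.squared))
  # any later entry matches anova() on the nested pair
  if (length(got$selected) > 1) {
    m1 <- lm(y ~ X[, got$selected[1]])
    m2 <- lm(y ~ X[, got$selected[1]] + X[, got$selected[2]])
    expect_equal(got$steps$F_change[2], anova(m1, m2)$F[2])
  }
})

test_that("stepwise entry rate under the null reflects family-wise alpha", {
  set.seed(34)
  hits <- vapply(1:1500, function(i) {
    X <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    length(stepwise_forward(X, rnorm(30))$selected) > 0
  }, logical(1))
  # at alpha = 0.05 per candidate and 6 candidates the family-wise entry
  # probability sits near 1 - 0.95^6 ~ 0.26 (slightly higher from selecting
  # the max); far above per-test alpha, well below half
  expect_gt(mean(hits), 0.18)
  expect_lt(mean(hits), 0.45)
})

test_that("the null-cohort simulator is deterministic with uniform p-values", {
  a <- simulate_null_contrast_scores(300, n_participants = 12, seed = 35)
  b <- simulate_null_contrast_scores(300, n_participants = 12, seed = 35)
  expect_identical(a$p_values, b$p_values)
  expect_true(all(a$p_values >= 0 & a$p_values <= 1))
  expect_equal(a$type1_at_05, mean(a$p_values < 0.05))
  # null p-values are roughly uniform
  expect_gt(mean(a$p_values), 0.42)
  expect_lt(mean(a$p_values), 0.58)
  # batching does not change the stream
  c2 <- simulate_null_contrast_scores(300, n_participants = 12, seed = 35,
                                      batch = 17)
  expect_identical(a$p_values, c2$p_values)
})
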