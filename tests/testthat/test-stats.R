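make_cycles <- function(pid, cond, trial, values, metric = "m") {
  data.frame(participant_id = pid, condition = cond, trial = trial,
             metric = metric, value = values)
}

test_that("averaging hierarchy is cycles-within-trial then trials-within-condition", {
  d <- rbind(make_cycles("P1", "a", 1, c(1, 2, 3)),
             make_cycles("P1", "a", 2, c(2, 4)))
  tab <- average_hierarchy(d)
  expect_equal(tab$value, mean(c(2, 3)))   # trial means 2 and 3, unweighted

  # unbalanced stride counts do not weight the trial means
  d2 <- rbind(make_cycles("P1", "a", 1, rep(10, 4)),
              make_cycles("P1", "a", 2, rep(0, 3)))
  expect_equal(average_hierarchy(d2)$value, 5)

  # single trial, single cycle passes through unchanged
  expect_equal(average_hierarchy(make_cycles("P1", "a", 1, 7))$value, 7)
})

test_that("a participant missing a condition is reported by name", {
  d <- rbind(make_cycles("P1", "a", 1, 1), make_cycles("P1", "b", 1, 2),
             make_cycles("P2", "a", 1, 3))
  tab <- average_hierarchy(d)
  expect_error(oneway_anova_tukey(tab, "m"), regexp = "P2.*b|b.*P2",
               class = "gaitdecomp_data_error")
})

test_that("KS screen accepts normal samples and rejects uniform ones", {
  set.seed(2024)
  ok <- replicate(100, ks_normality(rnorm(1000))$p > 0.05)
  expect_gte(mean(ok), 0.90)
  bad <- replicate(100, ks_normality(runif(1000))$p < 0.05)
  expect_gte(mean(bad), 0.90)
  expect_true(ks_normality(rep(4, 10))$degenerate)
})

test_that("a 16 x 4 cohort yields the (3, 60) ANOVA layout", {
  set.seed(9)
  d <- make_cycles(rep(sprintf("P%02d", 1:16), 4),
                   rep(c("w", "x", "y", "z"), each = 16), 1, rnorm(64))
  r <- oneway_anova_tukey(average_hierarchy(d), "m")
  expect_equal(r$df_effect, 3)
  expect_equal(r$df_error, 60)
  expect_equal(nrow(r$tukey), choose(4, 2))
  expect_gte(r$F, 0)
  expect_true(r$p >= 0 && r$p <= 1)
})

test_that("F and partial eta squared match the closed-form oracle on a small table", {
  # two conditions on three participants: hand-computable sums of squares
  vals <- c(1, 2, 3, 5, 6, 10)
  d <- make_cycles(rep(sprintf("P%d", 1:3), 2), rep(c("a", "b"), each = 3), 1, vals)
  r <- oneway_anova_tukey(average_hierarchy(d), "m")
  ga <- mean(vals[1:3]); gb <- mean(vals[4:6]); g <- mean(vals)
  ssb <- 3 * (ga - g)^2 + 3 * (gb - g)^2
  ssw <- sum((vals[1:3] - ga)^2) + sum((vals[4:6] - gb)^2)
  expect_equal(r$F, (ssb / 1) / (ssw / 4))
  expect_equal(r$partial_eta_sq, ssb / (ssb + ssw))
  expect_equal(r$df_effect, 1)
  expect_equal(r$df_error, 4)
})

test_that("identical values across all cells give F = 0 and no effect", {
  d <- make_cycles(rep(sprintf("P%02d", 1:16), 4),
                   rep(c("w", "x", "y", "z"), each = 16), 1, rep(2.5, 64))
  r <- oneway_anova_tukey(average_hierarchy(d), "m")
  expect_equal(r$F, 0)
  expect_equal(r$partial_eta_sq, 0)
  expect_equal(r$effect_label, "negligible")
  expect_false(any(r$tukey$significant))
})

test_that("partial eta squared is invariant to affine metric transforms", {
  set.seed(31)
  base <- rnorm(64)
  d1 <- make_cycles(rep(sprintf("P%02d", 1:16), 4),
                    rep(c("w", "x", "y", "z"), each = 16), 1, base)
  d2 <- d1; d2$value <- 3.2 * d1$value - 17
  r1 <- oneway_anova_tukey(average_hierarchy(d1), "m")
  r2 <- oneway_anova_tukey(average_hierarchy(d2), "m")
  expect_equal(r1$partial_eta_sq, r2$partial_eta_sq, tolerance = 1e-12)
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
})

test_that("effect-size labels follow the small/medium/large cut-offs", {
  expect_equal(effect_size_label(0.01), "negligible")
  expect_equal(effect_size_label(0.02), "small")
  expect_equal(effect_size_label(0.13), "medium")
  expect_equal(effect_size_label(0.26), "large")
  expect_equal(effect_size_label(0.36), "large")
})

test_that("repeated-measures variant removes the participant stratum", {
  set.seed(12)
  pid <- rep(sprintf("P%02d", 1:16), 4)
  d <- make_cycles(pid, rep(c("w", "x", "y", "z"), each = 16), 1,
                   rnorm(64) + rep(rnorm(16), 4))
  r <- oneway_anova_tukey(average_hierarchy(d), "m", repeated = TRUE)
  expect_equal(r$df_effect, 3)
  expect_equal(r$df_error, 45)
  expect_null(r$tukey)
})

test_that("null-effect data keep the ANOVA rejection rate near alpha", {
  set.seed(77)
  rej <- replicate(300, {
    d <- make_cycles(rep(sprintf("P%02d", 1:16), 4),
                     rep(c("w", "x", "y", "z"), each = 16), 1, rnorm(64))
    oneway_anova_tukey(average_hierarchy(d), "m")$p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("a null cohort from the generator shows no condition effect", {
  cfg <- synthetic_config(
    n_participants = 6, seed = 19, noise_sd_marker = 0, noise_sd_angle = 0.3,
    speed_shift = c(no_assistance = 0, afo = 0, newgait_dorsiflexion = 0,
                    newgait_full = 0),
    rom_means = matrix(rep(c(26.8, 35.7, 24.6, 9.6), each = 4), 4,
                       dimnames = dimnames(synthetic_config()$rom_means)),
    clearance_mean = c(no_assistance = 0.17, afo = 0.17,
                       newgait_dorsiflexion = 0.17, newgait_full = 0.17),
    pause_fractions = matrix(rep(c(0.16, 0.14, 0.21), 4), 3,
                             dimnames = dimnames(synthetic_config()$pause_fractions)))
  co <- generate_cohort(cfg)
  rows <- lapply(seq_along(co$trials), function(i)
    gaitdecomp:::.trial_per_cycle(co$trials[[i]], run_config()))
  tab <- average_hierarchy(do.call(rbind, rows))
  ps <- vapply(c("gait_velocity", "max_dorsiflexion", "hip_knee"),
               function(m) oneway_anova_tukey(tab, m)$p, numeric(1))
  expect_true(all(ps > 0.05))
})

test_that("paired comfort t-tests behave on degenerate, shifted and cohort data", {
  same <- data.frame(participant_id = sprintf("P%d", 1:10),
                     afo = rep(4, 10), newgait = rep(4, 10))
  r0 <- paired_t_bonferroni(same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)
  expect_false(r0$significant)

  set.seed(5)
  a <- rnorm(16, 5, 0.3)
  shifted <- data.frame(participant_id = sprintf("P%d", 1:16),
                        afo = a, newgait = a + 2 + rnorm(16, 0, 0.2))
  expect_true(paired_t_bonferroni(shifted)$significant)

  # the reference comfort profile (similar means, large SDs) is typically null
  scores <- generate_comfort_scores(16, seed = 2)
  rc <- paired_t_bonferroni(scores, alpha_adjusted = 0.03)
  expect_equal(nrow(rc), 3)
  expect_false(any(rc$significant))
})
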