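# Condition-comparison statistics: the stride -> trial -> condition
# averaging hierarchy, Kolmogorov-Smirnov normality screening, one-way
# ANOVA with Tukey HSD and partial eta squared, and Bonferroni-adjusted
# paired t-tests for comfort ratings.

#' Stride/trial averaging hierarchy
#'
#' Averages per-cycle metric values over cycles within each trial, then over
#' trials within each condition, unweighted at both levels (trials with
#' three and with four strides contribute equally).
#'
#' @param per_cycle Long data frame with columns `participant_id`,
#'   `condition`, `trial`, `metric`, `value` (one row per cycle).
#' @return Long data frame of class `cohort_table` with one row per
#'   participant x condition x metric.
#' @export
average_hierarchy <- function(per_cycle) {
  need <- c("participant_id", "condition", "trial", "metric", "value")
  missing <- setdiff(need, names(per_cycle))
  if (length(missing))
    gd_format_error(sprintf("per-cycle table lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  trial_means <- stats::aggregate(
    value ~ participant_id + condition + trial + metric,
    data = per_cycle, FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  cond_means <- stats::aggregate(
    value ~ participant_id + condition + metric,
    data = trial_means, FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  cond_means <- cond_means[order(cond_means$metric, cond_means$participant_id,
                                 cond_means$condition), ]
  rownames(cond_means) <- NULL
  class(cond_means) <- c("cohort_table", "data.frame")
  cond_means
}

# Wide participant x condition matrix for one metric; errors on missing cells.
.metric_cells <- function(table, metric) {
  d <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(d)) gd_data_error(sprintf("no values for metric '%s'", metric))
  participants <- unique(d$participant_id)
  conditions <- unique(d$condition)
  for (p in participants) for (cond in conditions) {
    if (!any(d$participant_id == p & d$condition == cond))
      gd_data_error(sprintf("missing data: participant %s has no '%s' value for condition %s",
                            p, metric, cond))
  }
  d
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic of the values against a normal distribution with
#' the sample's own mean and SD. Advisory only: the analysis pipeline
#' proceeds parametrically regardless. (Estimating the parameters from the
#' sample makes the nominal KS p-value conservative, the Lilliefors caveat.)
#'
#' @param values Numeric vector, `n >= 3`.
#' @return List with `statistic`, `p`, and `degenerate` (`TRUE` when the
#'   sample variance is zero and the test is skipped).
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) gd_data_error("normality screen needs at least 3 values")
  s <- sd(values)
  if (s < .Machine$double.eps^0.5)
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), s))
  list(statistic = unname(kt$statistic), p = kt$p.value, degenerate = FALSE)
}

#' Effect-size label for partial eta squared
#'
#' Cut-offs: small >= 0.02, medium >= 0.13, large >= 0.26.
#'
#' @param eta Partial eta squared in `[0, 1]`.
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`.
#' @export
effect_size_label <- function(eta) {
  if (is.na(eta)) return(NA_character_)
  if (eta >= 0.26) "large" else if (eta >= 0.13) "medium"
  else if (eta >= 0.02) "small" else "negligible"
}

#' One-way condition ANOVA with Tukey HSD and partial eta squared
#'
#' Treats each participant x condition mean as one observation in a one-way
#' between-cells ANOVA with factor condition, the convention of the
#' reference protocol (a 16 participant x 4 condition table yields
#' df = (3, 60)). Partial eta squared = SS_effect / (SS_effect + SS_error).
#' `repeated = TRUE` instead fits a repeated-measures ANOVA with a
#' participant error stratum (Tukey contrasts are only produced for the
#' default between-cells fit).
#'
#' @param table A `cohort_table` from [average_hierarchy()].
#' @param metric Metric name to analyze.
#' @param alpha Significance level.
#' @param repeated Use the repeated-measures error stratum.
#' @return Object of class `anova_result`: `F`, `df_effect`, `df_error`,
#'   `p`, `partial_eta_sq`, `effect_label`, `normality` (KS screen), and a
#'   `tukey` data frame (`pair`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`) for the default fit.
#' @export
oneway_anova_tukey <- function(table, metric, alpha = 0.05, repeated = FALSE) {
  d <- .metric_cells(table, metric)
  if (length(unique(d$condition)) < 2)
    gd_data_error("ANOVA needs at least 2 conditions")
  if (any(!is.finite(d$value)))
    gd_data_error(sprintf("metric '%s' contains non-finite condition means", metric))
  d$condition <- factor(d$condition, levels = unique(d$condition))
  norm <- ks_normality(d$value)

  if (var(d$value) < .Machine$double.eps) {
    # no variation anywhere: F defined as 0, no effect
    k <- nlevels(d$condition)
    tk <- data.frame(pair = .tukey_pairs(levels(d$condition)), diff = 0,
                     lwr = 0, upr = 0, p_adj = 1, significant = FALSE)
    return(structure(list(metric = metric, F = 0, df_effect = k - 1,
                          df_error = nrow(d) - k, p = 1, partial_eta_sq = 0,
                          effect_label = "negligible", normality = norm,
                          tukey = tk, alpha = alpha, repeated = repeated),
                     class = "anova_result"))
  }

  if (repeated) {
    d$participant_id <- factor(d$participant_id)
    fit <- aov(value ~ condition + Error(participant_id), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    ss_eff <- tab[1, "Sum Sq"]
    ss_err <- tab[nrow(tab), "Sum Sq"]
    res <- list(metric = metric, F = tab[1, "F value"],
                df_effect = tab[1, "Df"],
                df_error = tab[nrow(tab), "Df"],
                p = tab[1, "Pr(>F)"],
                partial_eta_sq = ss_eff / (ss_eff + ss_err),
                normality = norm, tukey = NULL, alpha = alpha, repeated = TRUE)
  } else {
    fit <- aov(value ~ condition, data = d)
    tab <- summary(fit)[[1]]
    ss_eff <- tab[1, "Sum Sq"]
    ss_err <- tab[nrow(tab), "Sum Sq"]
    tk_raw <- TukeyHSD(fit, conf.level = 1 - alpha)$condition
    tk <- data.frame(pair = rownames(tk_raw), diff = tk_raw[, "diff"],
                     lwr = tk_raw[, "lwr"], upr = tk_raw[, "upr"],
                     p_adj = tk_raw[, "p adj"],
                     significant = tk_raw[, "p adj"] < alpha,
                     row.names = NULL)
    res <- list(metric = metric, F = tab[1, "F value"],
                df_effect = tab[1, "Df"], df_error = tab[nrow(tab), "Df"],
                p = tab[1, "Pr(>F)"],
                partial_eta_sq = ss_eff / (ss_eff + ss_err),
                normality = norm, tukey = tk, alpha = alpha, repeated = FALSE)
  }
  res$effect_label <- effect_size_label(res$partial_eta_sq)
  structure(res, class = "anova_result")
}

.tukey_pairs <- function(levels) {
  cmb <- utils::combn(levels, 2)
  paste(cmb[2, ], cmb[1, ], sep = "-")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s: F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f (%s)\n",
              x$metric, x$df_effect, x$df_error, x$F, x$p, x$partial_eta_sq,
              x$effect_label))
  if (!is.null(x$tukey)) {
    sig <- x$tukey[x$tukey$significant, "pair"]
    cat("  Tukey significant pairs:",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Paired t-tests on comfort ratings with Bonferroni-adjusted alpha
#'
#' Three paired comparisons between the assisted conditions, each declared
#' significant at the supplied adjusted level (0.03 by default, matching the
#' reference protocol).
#'
#' @param scores Data frame with `participant_id` and one numeric column per
#'   assisted condition (at least two conditions).
#' @param alpha_adjusted Adjusted significance level.
#' @return Data frame with one row per pair: `pair`, `mean_diff`, `t`, `df`,
#'   `p`, `significant`, `degenerate`.
#' @export
paired_t_bonferroni <- function(scores, alpha_adjusted = 0.03) {
  conds <- setdiff(names(scores), "participant_id")
  if (length(conds) < 2) gd_data_error("need at least two condition columns")
  cmb <- utils::combn(conds, 2)
  out <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- scores[[cmb[1, i]]]
    b <- scores[[cmb[2, i]]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2) gd_data_error("need at least 2 complete pairs")
    dd <- a[ok] - b[ok]
    if (sd(dd) < .Machine$double.eps^0.5) {
      # zero-variance differences: degenerate, treated as no evidence
      return(data.frame(pair = paste(cmb[1, i], cmb[2, i], sep = " vs "),
                        mean_diff = mean(dd), t = 0, df = sum(ok) - 1,
                        p = 1, significant = FALSE, degenerate = TRUE))
    }
    tt <- t.test(a[ok], b[ok], paired = TRUE)
    data.frame(pair = paste(cmb[1, i], cmb[2, i], sep = " vs "),
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               significant = tt$p.value < alpha_adjusted, degenerate = FALSE)
  })
  do.call(rbind, out)
}
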