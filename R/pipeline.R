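# Pipeline orchestration: simulate -> analyze -> stats, with files as stage
# boundaries so each stage is independently testable and resumable. Every
# stage writes a manifest (config snapshot, seed, version, file hashes) so
# a run can be reproduced byte-for-byte.

.gd_metric_names <- c("gait_velocity", "step_length", "step_width",
                      "double_support", "foot_clearance",
                      "max_hip_flexion", "max_knee_flexion",
                      "max_dorsiflexion", "max_plantarflexion",
                      "hip_knee", "hip_ankle", "knee_ankle")

write_manifest <- function(dir, stage, config, files) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("gaitdecomp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Simulate a cohort and write it to disk
#'
#' Generates the synthetic cohort and writes one canonical trial file per
#' trial, a ground-truth JSON next to each, and a run manifest.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param format Trial file format (`"canonical_csv"` or `"trc"`).
#' @return Invisibly, the manifest list.
#' @export
simulate_cohort <- function(config = synthetic_config(), out_dir,
                            format = c("canonical_csv", "trc")) {
  format <- match.arg(format)
  config <- validate_synthetic_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gd_log("simulate", "info",
         sprintf("generating cohort: %d participants, seed %d",
                 config$n_participants, config$seed))
  cohort <- generate_cohort(config)
  ext <- if (format == "canonical_csv") "csv" else "trc"
  paths <- character(0)
  for (i in seq_along(cohort$trials)) {
    rec <- cohort$trials[[i]]
    base <- sprintf("%s_%s_t%02d", rec$participant_id, rec$condition, rec$trial)
    trial_path <- file.path(out_dir, paste0(base, ".", ext))
    write_trial(rec, trial_path, format = format)
    truth_path <- file.path(out_dir, paste0(base, ".truth.json"))
    jsonlite::write_json(cohort$truth[[i]], truth_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    paths <- c(paths, trial_path, truth_path)
  }
  gd_log("simulate", "info", sprintf("wrote %d trials to %s",
                                     length(cohort$trials), out_dir))
  invisible(write_manifest(out_dir, "simulate",
                           config = unclass(config), files = paths))
}

# All per-cycle metrics of one trial, long format, paretic side.
.trial_per_cycle <- function(rec, config) {
  ev <- detect_events(rec, filter_cutoff = config$filter_cutoff)
  side <- rec$paretic_side
  cycles <- segment_cycles(ev, side)
  st <- spatiotemporal(rec, ev, side, filter_cutoff = config$filter_cutoff)
  ang <- compute_sagittal_angles(rec, sides = side)[[side]]
  # extrema are read from low-pass filtered angles so marker noise does not
  # inflate the per-cycle maxima; decomposition filters internally
  ang_f <- ang
  for (j in c("hip", "knee", "ankle"))
    ang_f[[j]] <- lowpass(ang[[j]], rec$sample_rate, config$filter_cutoff)
  km <- kinematic_maxima(ang_f, cycles)
  dc <- decomposition_all_pairs(ang, cycles, config)
  wide <- cbind(st, km[, -1, drop = FALSE], dc$per_cycle[, -1, drop = FALSE])
  long <- stats::reshape(wide, direction = "long",
                         varying = list(setdiff(names(wide), "cycle")),
                         v.names = "value", timevar = "metric",
                         times = setdiff(names(wide), "cycle"))
  data.frame(participant_id = rec$participant_id, condition = rec$condition,
             trial = if (is.na(rec$trial)) 1L else rec$trial,
             side = side, cycle = long$cycle, metric = long$metric,
             value = long$value, row.names = NULL)
}

#' Analyze a directory of trials into a tidy per-cycle metrics table
#'
#' Reads every trial file, detects events, computes the spatiotemporal,
#' kinematic and decomposition metrics on the paretic side, and writes one
#' tidy CSV row per participant x condition x trial x cycle x metric.
#' Unreadable or unanalyzable trials are logged and skipped; the stage
#' fails when more than `max_skip_fraction` of the trials were skipped.
#'
#' @param in_dir Directory holding trial files.
#' @param out_path Output CSV path.
#' @param config A [run_config()].
#' @param format Trial file format to read.
#' @param max_skip_fraction Largest tolerated fraction of skipped trials.
#' @return Invisibly, the per-cycle data frame.
#' @export
analyze_trials <- function(in_dir, out_path, config = run_config(),
                           format = c("canonical_csv", "trc"),
                           max_skip_fraction = 0.1) {
  format <- match.arg(format)
  ext <- if (format == "canonical_csv") "\\.csv$" else "\\.trc$"
  files <- list.files(in_dir, pattern = ext, full.names = TRUE)
  files <- files[!grepl("manifest|metrics", basename(files))]
  if (!length(files)) gd_data_error(sprintf("no trial files found in %s", in_dir))
  rows <- list()
  skipped <- 0L
  for (f in files) {
    res <- tryCatch({
      rec <- read_trial(f, format = format, max_gap = config$max_gap)
      .trial_per_cycle(rec, config)
    }, gaitdecomp_error = function(e) {
      gd_log("analyze", "warn", sprintf("skipping %s: %s",
                                        basename(f), conditionMessage(e)))
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else rows[[length(rows) + 1]] <- res
  }
  if (skipped > max_skip_fraction * length(files))
    gd_data_error(sprintf("%d of %d trials skipped (more than %.0f%%)",
                          skipped, length(files), 100 * max_skip_fraction))
  out <- do.call(rbind, rows)
  write_metrics_table(out, out_path)
  gd_log("analyze", "info",
         sprintf("analyzed %d/%d trials -> %s (%d rows)",
                 length(files) - skipped, length(files), out_path, nrow(out)))
  write_manifest(dirname(out_path), "analyze", config = unclass(config),
                 files = out_path)
  invisible(out)
}

#' Condition-comparison statistics over a metrics table
#'
#' Applies the averaging hierarchy, runs the per-metric condition ANOVA with
#' Tukey HSD and partial eta squared, and writes (a) a JSON stats report and
#' (b) a formatted mean +/- SD condition table with significance markers
#' (`*` different from the unassisted condition, `**` different from the
#' AFO condition, both by Tukey HSD at the configured alpha).
#'
#' @param metrics_csv Tidy per-cycle metrics CSV from [analyze_trials()].
#' @param out_json Output JSON path.
#' @param out_table Optional output CSV path for the formatted table.
#' @param config A [run_config()].
#' @param comfort Optional comfort-score data frame for
#'   [paired_t_bonferroni()].
#' @return Invisibly, a list with `anova` (per-metric `anova_result`s),
#'   `table` (formatted data frame) and `comfort` results.
#' @export
stats_report <- function(metrics_csv, out_json, out_table = NULL,
                         config = run_config(), comfort = NULL) {
  per_cycle <- read.csv(metrics_csv)
  tab <- average_hierarchy(per_cycle)
  metrics <- intersect(.gd_metric_names, unique(tab$metric))
  res <- lapply(metrics, function(m)
    oneway_anova_tukey(tab, m, alpha = config$alpha))
  names(res) <- metrics
  fmt <- format_condition_table(tab, res)
  comfort_res <- if (!is.null(comfort))
    paired_t_bonferroni(comfort, alpha_adjusted = config$comfort_alpha)

  json <- lapply(res, function(r) list(
    F = r$F, df = c(r$df_effect, r$df_error), p = r$p,
    partial_eta_sq = r$partial_eta_sq, label = r$effect_label,
    normality = r$normality,
    tukey = r$tukey))
  payload <- list(metrics = json)
  if (!is.null(comfort_res)) payload$comfort <- comfort_res
  jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, dataframe = "rows")
  if (!is.null(out_table)) write_metrics_table(fmt, out_table)
  gd_log("stats", "info", sprintf("%d metric blocks -> %s", length(res), out_json))
  invisible(list(anova = res, table = fmt, comfort = comfort_res))
}

#' Formatted mean +/- SD condition table
#'
#' One row per metric, one column per condition, each cell
#' `"mean ± SD"`; Tukey-based significance markers appended (`*` vs the
#' first condition, `**` vs the second), mirroring the conventional
#' condition-table layout.
#'
#' @param tab A `cohort_table`.
#' @param anova_results Named list of `anova_result` objects.
#' @return Data frame (`metric` + one column per condition).
#' @export
format_condition_table <- function(tab, anova_results) {
  conditions <- unique(tab$condition)
  known <- intersect(.gd_conditions, conditions)
  conditions <- c(known, setdiff(conditions, known))
  metrics <- intersect(.gd_metric_names, unique(tab$metric))
  ref1 <- conditions[1]
  ref2 <- if (length(conditions) > 1) conditions[2] else NULL
  rows <- lapply(metrics, function(m) {
    d <- tab[tab$metric == m, ]
    r <- anova_results[[m]]
    cells <- vapply(conditions, function(cond) {
      v <- d$value[d$condition == cond]
      cell <- sprintf("%s ± %s", signif(mean(v), 3), signif(sd(v), 3))
      if (!is.null(r$tukey) && cond != ref1) {
        if (.tukey_sig(r$tukey, cond, ref1)) cell <- paste0(cell, "*")
        if (!is.null(ref2) && cond != ref2 && .tukey_sig(r$tukey, cond, ref2))
          cell <- paste0(cell, "**")
      }
      cell
    }, character(1))
    c(metric = m, cells)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- NULL
  out
}

.tukey_sig <- function(tukey, a, b) {
  hit <- tukey$pair %in% c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))
  any(tukey$significant[hit])
}

#' Run the full pipeline: simulate, analyze, stats
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory; trials go to `out_dir/trials`, results
#'   to `out_dir/`.
#' @param run_cfg A [run_config()].
#' @return Invisibly, the [stats_report()] result.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir,
                         run_cfg = run_config()) {
  trial_dir <- file.path(out_dir, "trials")
  simulate_cohort(config, trial_dir)
  metrics_csv <- file.path(out_dir, "metrics.csv")
  analyze_trials(trial_dir, metrics_csv, config = run_cfg)
  comfort <- generate_comfort_scores(config$n_participants,
                                     seed = config$seed + 1L)
  stats_report(metrics_csv, file.path(out_dir, "stats.json"),
               out_table = file.path(out_dir, "condition_table.csv"),
               config = run_cfg, comfort = comfort)
}
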