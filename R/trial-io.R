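# Trial containers and file formats: a strict canonical CSV dialect plus TRC
# import/export. Marker coordinates are meters in the lab frame (X = forward
# progression, Y = mediolateral with left positive, Z = up).

.gd_leg_markers <- c("hip", "knee", "ankle", "heel", "toe")

#' Motion-capture trial container
#'
#' One walking trial: named marker trajectories (N x 3 matrices, meters),
#' sample rate, and participant/condition metadata. The full analyzable
#' marker set is `sacrum` plus `hip`, `knee`, `ankle`, `heel`, `toe` for
#' each side (`_L` / `_R` suffix).
#'
#' @param markers Named list of N x 3 numeric matrices (columns X, Y, Z).
#' @param sample_rate Sampling rate, Hz.
#' @param participant_id Participant label.
#' @param condition Walking-condition label.
#' @param paretic_side `"left"` or `"right"`.
#' @param trial Trial number (optional).
#' @param validate Check invariants (equal lengths, no missing values,
#'   plausible Z).
#' @return Object of class `trial_recording`.
#' @export
trial_recording <- function(markers, sample_rate, participant_id = "unknown",
                            condition = "unknown", paretic_side = "left",
                            trial = NA_integer_, validate = TRUE) {
  rec <- structure(list(markers = markers, sample_rate = sample_rate,
                        participant_id = participant_id, condition = condition,
                        paretic_side = paretic_side, trial = trial),
                   class = "trial_recording")
  if (validate) validate_trial_recording(rec)
  rec
}

validate_trial_recording <- function(rec) {
  if (!length(rec$markers)) gd_format_error("recording holds no markers")
  ns <- vapply(rec$markers, nrow, integer(1))
  if (length(unique(ns)) != 1)
    gd_format_error("all marker series must have the same length")
  if (ns[1] < 2) gd_format_error("recording must span at least 2 frames")
  if (!is.numeric(rec$sample_rate) || rec$sample_rate <= 0)
    gd_format_error("sample_rate must be positive")
  if (!rec$paretic_side %in% c("left", "right"))
    gd_format_error("paretic_side must be 'left' or 'right'")
  for (nm in names(rec$markers)) {
    m <- rec$markers[[nm]]
    if (anyNA(m)) gd_data_error(sprintf("marker %s contains missing values", nm))
    if (any(m[, 3] < -0.01))
      gd_data_error(sprintf("marker %s drops below the floor (Z < -0.01 m)", nm))
  }
  invisible(rec)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s / %s%s: %d markers x %d frames @ %g Hz, paretic %s\n",
              x$participant_id, x$condition,
              if (is.na(x$trial)) "" else sprintf(" (trial %d)", x$trial),
              length(x$markers), nrow(x$markers[[1]]), x$sample_rate,
              x$paretic_side))
  invisible(x)
}

n_frames <- function(rec) nrow(rec$markers[[1]])

# Required marker names for analysing `side` ("left"/"right").
required_markers <- function(side = c("left", "right")) {
  side <- match.arg(side)
  c("sacrum", paste0(.gd_leg_markers, if (side == "left") "_L" else "_R"))
}

check_required_markers <- function(rec, sides = c("left", "right")) {
  need <- unique(unlist(lapply(sides, required_markers)))
  missing <- setdiff(need, names(rec$markers))
  if (length(missing))
    gd_format_error(sprintf("required marker absent: %s",
                            paste(missing, collapse = ", ")))
  invisible(rec)
}

#' Write a trial to disk
#'
#' Canonical CSV dialect: a `#`-prefixed metadata block (`sample_rate`,
#' `participant_id`, `condition`, `paretic_side`, `trial`, `units: m`), then
#' a header row `time,<marker>_<X|Y|Z>,...` and one row per frame. TRC
#' writes the standard tab-separated TRC header and data blocks.
#'
#' @param recording A [trial_recording].
#' @param path Output file path.
#' @param format `"canonical_csv"` or `"trc"`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(recording, path, format = c("canonical_csv", "trc")) {
  format <- match.arg(format)
  validate_trial_recording(recording)
  if (format == "canonical_csv") .write_trial_csv(recording, path)
  else .write_trial_trc(recording, path)
  invisible(path)
}

.write_trial_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gaitdecomp_trial v1",
               sprintf("# sample_rate: %.10g", rec$sample_rate),
               sprintf("# participant_id: %s", rec$participant_id),
               sprintf("# condition: %s", rec$condition),
               sprintf("# paretic_side: %s", rec$paretic_side),
               sprintf("# trial: %s", ifelse(is.na(rec$trial), "NA", rec$trial)),
               "# units: m"), con)
  n <- n_frames(rec)
  cols <- list(time = (seq_len(n) - 1) / rec$sample_rate)
  for (nm in names(rec$markers)) for (j in 1:3)
    cols[[paste0(nm, "_", c("X", "Y", "Z")[j])]] <- rec$markers[[nm]][, j]
  df <- as.data.frame(cols, check.names = FALSE)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
}

.write_trial_trc <- function(rec, path) {
  n <- n_frames(rec)
  nm <- names(rec$markers)
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames"
  l3 <- sprintf("%.10g\t%.10g\t%d\t%d\tm\t%.10g\t1\t%d",
                rec$sample_rate, rec$sample_rate, n, length(nm), rec$sample_rate, n)
  l4 <- paste(c("Frame#", "Time", vapply(nm, function(x) paste0(x, "\t"), "")),
              collapse = "\t")
  l5 <- paste(c("", "", paste0(c("X", "Y", "Z"), rep(seq_along(nm), each = 3))),
              collapse = "\t")
  dat <- do.call(cbind, rec$markers)
  body <- vapply(seq_len(n), function(i)
    paste(c(i, sprintf("%.10g", (i - 1) / rec$sample_rate),
            sprintf("%.10g", dat[i, ])), collapse = "\t"), "")
  writeLines(c(l1, l2, l3, l4, l5, "", body), path)
}

#' Read a trial from disk
#'
#' Reads the canonical CSV dialect (strict: metadata block with
#' `sample_rate`, unit declaration `m`, exact coordinate-column triplets) or
#' a TRC file (positions and rate only). Marker gaps up to `max_gap` frames
#' are linearly interpolated; longer gaps raise a data-quality error naming
#' the frame range. C3D is not supported; convert to TRC or CSV.
#'
#' @param path Input file.
#' @param format `"canonical_csv"`, `"trc"`, or `"c3d"` (rejected with an
#'   informative error).
#' @param max_gap Longest marker dropout (frames) bridged by interpolation.
#' @param require_markers Validate that the full two-sided marker set is
#'   present.
#' @return A [trial_recording].
#' @export
read_trial <- function(path, format = c("canonical_csv", "trc", "c3d"),
                       max_gap = 10L, require_markers = TRUE) {
  format <- match.arg(format)
  if (format == "c3d")
    gd_format_error("C3D import is not supported; export the trial as TRC or canonical CSV")
  if (!file.exists(path)) gd_format_error(sprintf("file not found: %s", path))
  rec <- if (format == "canonical_csv") .read_trial_csv(path, max_gap)
         else .read_trial_trc(path, max_gap)
  if (require_markers) check_required_markers(rec)
  validate_trial_recording(rec)
  rec
}

.read_trial_csv <- function(path, max_gap) {
  lines <- readLines(path, n = 64)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("gaitdecomp_trial", hdr[1]))
    gd_format_error(sprintf("%s: not a gaitdecomp canonical trial CSV", basename(path)))
  meta <- list()
  for (h in hdr[-1]) {
    kv <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- trimws(kv[3])
  }
  if (is.null(meta$sample_rate))
    gd_format_error(sprintf("%s: metadata block lacks sample_rate", basename(path)))
  if (!identical(meta$units, "m"))
    gd_format_error(sprintf("%s: units must be declared as 'm'", basename(path)))
  rate <- as.numeric(meta$sample_rate)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1] != "time")
    gd_format_error(sprintf("%s: first column must be 'time'", basename(path)))
  coord_cols <- names(df)[-1]
  bad <- coord_cols[!grepl("_(X|Y|Z)$", coord_cols)]
  if (length(bad))
    gd_format_error(sprintf("%s: unexpected columns: %s", basename(path),
                            paste(bad, collapse = ", ")))
  mk_names <- unique(sub("_(X|Y|Z)$", "", coord_cols))
  markers <- list()
  for (nm in mk_names) {
    need <- paste0(nm, "_", c("X", "Y", "Z"))
    if (!all(need %in% coord_cols))
      gd_format_error(sprintf("%s: incomplete coordinate triplet for marker %s",
                              basename(path), nm))
    m <- as.matrix(df[, need])
    colnames(m) <- c("X", "Y", "Z")
    for (j in 1:3) m[, j] <- fill_gaps(m[, j], max_gap,
                                       what = paste0(nm, "_", c("X", "Y", "Z")[j]))
    markers[[nm]] <- m
  }
  trial_recording(markers = markers, sample_rate = rate,
                  participant_id = meta$participant_id %||% "unknown",
                  condition = meta$condition %||% "unknown",
                  paretic_side = meta$paretic_side %||% "left",
                  trial = suppressWarnings(as.integer(meta$trial %||% NA)),
                  validate = FALSE)
}

.read_trial_trc <- function(path, max_gap) {
  lines <- readLines(path)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1]))
    gd_format_error(sprintf("%s: not a TRC file", basename(path)))
  vals <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(vals[1])
  if (!is.finite(rate) || rate <= 0)
    gd_format_error(sprintf("%s: invalid DataRate", basename(path)))
  mk_names <- strsplit(lines[4], "\t")[[1]]
  mk_names <- mk_names[!mk_names %in% c("Frame#", "Time", "")]
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  dat <- do.call(rbind, lapply(strsplit(body, "\t"), function(x)
    suppressWarnings(as.numeric(x))))
  if (ncol(dat) != 2 + 3 * length(mk_names))
    gd_format_error(sprintf("%s: data columns do not match marker count", basename(path)))
  markers <- list()
  for (i in seq_along(mk_names)) {
    m <- dat[, (3 * (i - 1) + 3):(3 * (i - 1) + 5), drop = FALSE]
    colnames(m) <- c("X", "Y", "Z")
    for (j in 1:3) m[, j] <- fill_gaps(m[, j], max_gap,
                                       what = paste0(mk_names[i], "_", c("X", "Y", "Z")[j]))
    markers[[mk_names[i]]] <- m
  }
  trial_recording(markers = markers, sample_rate = rate, validate = FALSE)
}

#' Write a tidy metrics table as CSV
#' @param table Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# Run configuration -----------------------------------------------------------

.run_config_schema <- c("pause_threshold_fraction", "velocity_floor",
                        "filter_cutoff", "alpha", "comfort_alpha", "seed",
                        "max_gap", "paths")

#' Analysis run configuration
#'
#' Thresholds and settings of the analysis stages. The defaults mirror the
#' reference protocol: a joint counts as paused when its angular velocity
#' drops below 5% of the cycle's peak (baseline) velocity; ANOVA alpha 0.05;
#' Bonferroni-adjusted comfort-score alpha 0.03.
#'
#' @param pause_threshold_fraction Pause threshold as a fraction of the
#'   baseline (per-cycle peak) angular velocity; in (0, 1).
#' @param velocity_floor Absolute velocity floor in deg/s: a joint whose
#'   baseline velocity is below it counts as frozen for the whole cycle.
#' @param filter_cutoff Low-pass cutoff (Hz) used before differentiation and
#'   event detection; `NULL` disables filtering.
#' @param alpha Significance level of the condition ANOVA.
#' @param comfort_alpha Adjusted significance level of the paired
#'   comfort-score t-tests.
#' @param seed RNG seed for stochastic stages.
#' @param max_gap Longest marker dropout (frames) bridged on import.
#' @param paths Optional named list of input/output paths.
#' @return Object of class `run_config`.
#' @export
run_config <- function(pause_threshold_fraction = 0.05, velocity_floor = 1.0,
                       filter_cutoff = 6, alpha = 0.05, comfort_alpha = 0.03,
                       seed = 1L, max_gap = 10L, paths = list()) {
  cfg <- structure(list(pause_threshold_fraction = pause_threshold_fraction,
                        velocity_floor = velocity_floor,
                        filter_cutoff = filter_cutoff, alpha = alpha,
                        comfort_alpha = comfort_alpha, seed = as.integer(seed),
                        max_gap = as.integer(max_gap), paths = paths),
                   class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, key, what)
    if (!ok) gd_config_error(sprintf("invalid config key '%s': %s", key, what))
  chk(is.numeric(cfg$pause_threshold_fraction) &&
        cfg$pause_threshold_fraction > 0 && cfg$pause_threshold_fraction < 1,
      "pause_threshold_fraction", "must lie in (0, 1)")
  chk(is.numeric(cfg$velocity_floor) && cfg$velocity_floor >= 0,
      "velocity_floor", "must be >= 0")
  chk(is.null(cfg$filter_cutoff) ||
        (is.numeric(cfg$filter_cutoff) && cfg$filter_cutoff > 0),
      "filter_cutoff", "must be positive or NULL")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha", "must lie in (0, 1)")
  chk(is.numeric(cfg$comfort_alpha) && cfg$comfort_alpha > 0 && cfg$comfort_alpha < 1,
      "comfort_alpha", "must lie in (0, 1)")
  chk(cfg$max_gap >= 0, "max_gap", "must be >= 0")
  cfg
}

#' Load a run configuration from YAML
#'
#' Strict schema: unknown keys are rejected, and every value is validated
#' with the offending key named in the error.
#'
#' @param path YAML file.
#' @return A [run_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) gd_config_error(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .run_config_schema)
  if (length(unknown))
    gd_config_error(sprintf("unknown config key: %s", paste(unknown, collapse = ", ")))
  do.call(run_config, raw)
}
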