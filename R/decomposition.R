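# The gait decomposition index: per-joint pause detection by a relative
# angular-velocity threshold, and the percentage of the gait cycle during
# which exactly one joint of a pair moves while the other is paused.
# 0% = the two joints move simultaneously; 100% = one joint moves alone.

#' Angular velocity of a joint-angle series
#'
#' Central finite difference of the (optionally low-pass filtered) angle
#' series, multiplied by the sample rate; one-sided differences at the ends
#' keep the output the same length as the input. Filtering (6 Hz zero-phase
#' Butterworth by default) suppresses marker-noise-induced velocity
#' fragmentation; pass `filter_cutoff = NULL` for noise-free signals.
#'
#' @param angles Numeric vector of angles (degrees) or a
#'   [joint_angle_series].
#' @param sample_rate Hz; taken from the series when omitted.
#' @param filter_cutoff Low-pass cutoff in Hz, or `NULL` for none.
#' @return Velocity in deg/s: a numeric vector, or a named list of vectors
#'   (`hip`, `knee`, `ankle`) for a series.
#' @export
angular_velocity <- function(angles, sample_rate = NULL, filter_cutoff = 6) {
  if (inherits(angles, "joint_angle_series")) {
    rate <- sample_rate %||% angles$sample_rate
    return(lapply(angles[c("hip", "knee", "ankle")], angular_velocity,
                  sample_rate = rate, filter_cutoff = filter_cutoff))
  }
  if (is.null(sample_rate)) gd_config_error("sample_rate required for a bare vector")
  if (length(angles) < 3) gd_domain_error("need at least 3 samples for angular velocity")
  central_diff(lowpass(angles, sample_rate, filter_cutoff)) * sample_rate
}

#' Pause mask of one joint over one cycle
#'
#' A joint counts as paused at a frame when its absolute angular velocity
#' drops below `fraction` of the baseline velocity, the joint's peak
#' absolute angular velocity within the cycle. A joint whose baseline falls
#' below the absolute `floor` is frozen: it is paused for the entire cycle
#' (a purely relative threshold is degenerate when the joint barely moves).
#'
#' @param velocity Numeric velocity series, deg/s.
#' @param cycle Half-open `[start, end)` frame interval; `NULL` uses the
#'   whole series.
#' @param fraction Threshold fraction of the baseline velocity, in (0, 1).
#' @param floor Frozen-joint floor, deg/s.
#' @return Object of class `pause_mask`: logical `mask` over the cycle plus
#'   the `baseline` and `threshold` (deg/s) used.
#' @export
pause_mask <- function(velocity, cycle = NULL, fraction = 0.05, floor = 1.0) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    gd_domain_error("pause threshold fraction must lie in (0, 1)")
  if (floor < 0) gd_domain_error("velocity floor must be >= 0")
  v <- if (is.null(cycle)) velocity else velocity[cycle[1]:(cycle[2] - 1)]
  baseline <- max(abs(v))
  if (baseline < floor) {
    mask <- rep(TRUE, length(v))
    threshold <- floor
  } else {
    threshold <- fraction * baseline
    mask <- abs(v) < threshold
  }
  structure(list(mask = mask, baseline = baseline, threshold = threshold,
                 fraction = fraction, floor = floor),
            class = "pause_mask")
}

#' @export
print.pause_mask <- function(x, ...) {
  cat(sprintf("<pause_mask> %d frames, %.1f%% paused (baseline %.1f deg/s, threshold %.2f deg/s)\n",
              length(x$mask), 100 * mean(x$mask), x$baseline, x$threshold))
  invisible(x)
}

#' Decomposition index of a joint pair
#'
#' Percentage of the gait cycle during which exactly one joint of the pair
#' is paused while the other moves. Frames where both joints are paused are
#' excluded from the count and from the cycle-time base (neither joint is
#' "in motion" there); if every frame is both-paused the index is 0. The
#' index is symmetric in the pair's order and bounded in `[0, 100]`.
#'
#' @param mask_a,mask_b [pause_mask] objects (or logical vectors) over the
#'   same cycle.
#' @return Percentage in `[0, 100]`.
#' @export
decomposition_index <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "pause_mask")) mask_a$mask else as.logical(mask_a)
  b <- if (inherits(mask_b, "pause_mask")) mask_b$mask else as.logical(mask_b)
  if (length(a) != length(b))
    gd_error("gaitdecomp_internal_error", "pause masks have different lengths")
  keep <- !(a & b)
  if (!any(keep)) return(0)
  100 * sum(xor(a, b)) / sum(keep)
}

.gd_pairs <- list(hip_knee = c("hip", "knee"),
                  hip_ankle = c("hip", "ankle"),
                  knee_ankle = c("knee", "ankle"))

#' Decomposition indices for the three joint pairs
#'
#' Computes per-cycle pause masks for hip, knee and ankle (baseline velocity
#' normalized per cycle and per joint) and the decomposition index of each
#' pair (hip-knee, hip-ankle, knee-ankle), then averages over cycles.
#'
#' @param angles A [joint_angle_series] for the analyzed (paretic) leg.
#' @param cycles Two-column matrix of half-open cycle intervals.
#' @param config A [run_config()] supplying `pause_threshold_fraction`,
#'   `velocity_floor` and `filter_cutoff`.
#' @return Object of class `decomposition_result`: `per_cycle` data frame
#'   (`cycle`, `hip_knee`, `hip_ankle`, `knee_ankle`, percentages),
#'   `trial_mean` named vector, and the threshold `params` used.
#' @export
decomposition_all_pairs <- function(angles, cycles, config = run_config()) {
  stopifnot(inherits(angles, "joint_angle_series"))
  if (is.vector(cycles)) cycles <- matrix(cycles, 1, 2)
  if (nrow(cycles) < 1) gd_data_error("need at least one complete cycle")
  vel <- angular_velocity(angles, filter_cutoff = config$filter_cutoff)
  per <- lapply(seq_len(nrow(cycles)), function(i) {
    cyc <- cycles[i, ]
    masks <- lapply(vel, pause_mask, cycle = cyc,
                    fraction = config$pause_threshold_fraction,
                    floor = config$velocity_floor)
    vals <- vapply(.gd_pairs, function(p)
      decomposition_index(masks[[p[1]]], masks[[p[2]]]), numeric(1))
    data.frame(cycle = i, t(vals))
  })
  per <- do.call(rbind, per)
  structure(list(
    per_cycle = per,
    trial_mean = colMeans(per[, names(.gd_pairs), drop = FALSE]),
    params = list(pause_threshold_fraction = config$pause_threshold_fraction,
                  velocity_floor = config$velocity_floor,
                  filter_cutoff = config$filter_cutoff)),
    class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> %d cycle(s); trial means: hip-knee %.1f%%, hip-ankle %.1f%%, knee-ankle %.1f%%\n",
              nrow(x$per_cycle), x$trial_mean[["hip_knee"]],
              x$trial_mean[["hip_ankle"]], x$trial_mean[["knee_ankle"]]))
  invisible(x)
}
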