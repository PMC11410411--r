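# Sagittal joint angles from a planar marker model and the five
# spatiotemporal gait characteristics. Angles use the clinical sign
# convention: hip flexion +, knee flexion +, ankle dorsiflexion +,
# plantarflexion - (reported as a positive magnitude in the maxima).

.seg_angle_from_vertical <- function(dx, dz, what) {
  len <- sqrt(dx^2 + dz^2)
  if (any(len < 1e-6))
    gd_data_error(sprintf("degenerate (zero-length) %s segment at frame %d",
                          what, which(len < 1e-6)[1]))
  atan2(dx, -dz)
}

#' Sagittal hip, knee and ankle angles from markers
#'
#' Planar two-segment model in the progression (X-Z) plane: hip flexion is
#' the thigh's inclination from vertical, knee flexion the angle between
#' thigh and shank, and the ankle angle the foot's pitch relative to the
#' shank (perpendicular = 0, dorsiflexion positive).
#'
#' @param recording A [trial_recording] with the full marker set.
#' @param sides Which sides to compute (default both).
#' @return Named list (`left`, `right`) of [joint_angle_series].
#' @export
compute_sagittal_angles <- function(recording, sides = c("left", "right")) {
  check_required_markers(recording, sides)
  R <- progression_rotation(recording)
  out <- list()
  for (side in sides) {
    sfx <- if (side == "left") "_L" else "_R"
    g <- function(nm) rotate_marker(recording$markers[[paste0(nm, sfx)]], R)
    hip <- g("hip"); knee <- g("knee"); ankle <- g("ankle")
    heel <- g("heel"); toe <- g("toe")
    th_t <- .seg_angle_from_vertical(knee[, 1] - hip[, 1], knee[, 3] - hip[, 3], "thigh")
    th_s <- .seg_angle_from_vertical(ankle[, 1] - knee[, 1], ankle[, 3] - knee[, 3], "shank")
    fx <- toe[, 1] - heel[, 1]
    fz <- toe[, 3] - heel[, 3]
    flen <- sqrt(fx^2 + fz^2)
    if (any(flen < 1e-6))
      gd_data_error(sprintf("degenerate (zero-length) foot segment at frame %d",
                            which(flen < 1e-6)[1]))
    pitch <- atan2(fz, fx)
    deg <- 180 / pi
    out[[side]] <- joint_angle_series(hip = th_t * deg,
                                      knee = (th_t - th_s) * deg,
                                      ankle = (pitch - th_s) * deg,
                                      sample_rate = recording$sample_rate,
                                      side = side)
  }
  out
}

# Per-side stance indicator over the whole trial from contact/toe-off
# sequences: in stance from each contact until the next toe-off.
.stance_indicator <- function(contacts, toeoffs, n) {
  ev <- rbind(if (length(contacts)) cbind(contacts, 1L),
              if (length(toeoffs)) cbind(toeoffs, 0L))
  if (is.null(ev) || nrow(ev) == 0) return(rep(NA, n))
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  state <- rep(NA, n)
  cur <- NA
  j <- 1
  for (i in seq_len(n)) {
    while (j <= nrow(ev) && ev[j, 1] <= i) { cur <- ev[j, 2] == 1L; j <- j + 1 }
    state[i] <- cur
  }
  # before the first event, assume the opposite of the first event's result
  first_ev <- ev[1, ]
  state[seq_len(min(n, first_ev[1] - 1))] <- !(first_ev[2] == 1L)
  state
}

#' Spatiotemporal gait characteristics per cycle
#'
#' For each complete cycle on `side`: gait velocity (sacrum horizontal path
#' length over the cycle duration), step length (anterior heel-to-heel
#' distance at each foot contact, ipsi- and contralateral steps averaged),
#' step width (mediolateral heel-to-heel distance at the same contacts),
#' double support (% of the cycle with both feet in stance) and foot
#' clearance (peak swing toe height above the foot-flat stance baseline).
#'
#' Marker trajectories are low-pass filtered (`filter_cutoff`) before the
#' path-length and peak-height computations: summed increments and extrema
#' are otherwise inflated by uncorrelated marker noise.
#'
#' @param recording A [trial_recording].
#' @param events A `gait_cycle_set` from [detect_events()].
#' @param side Analyzed side; defaults to the recording's paretic side.
#' @param filter_cutoff Low-pass cutoff in Hz (`NULL` to skip filtering).
#' @return Data frame with one row per cycle (`cycle`, `gait_velocity`,
#'   `step_length`, `step_width`, `double_support`, `foot_clearance`) and a
#'   `"stride_average"` attribute with the per-trial means.
#' @export
spatiotemporal <- function(recording, events, side = NULL, filter_cutoff = 6) {
  side <- side %||% recording$paretic_side
  other <- if (side == "left") "right" else "left"
  rate <- recording$sample_rate
  cycles <- segment_cycles(events, side)
  R <- progression_rotation(recording)
  sac <- rotate_marker(recording$markers[["sacrum"]], R)
  sfx <- function(s) if (s == "left") "_L" else "_R"
  heel_i <- rotate_marker(recording$markers[[paste0("heel", sfx(side))]], R)
  heel_c <- rotate_marker(recording$markers[[paste0("heel", sfx(other))]], R)
  toe_i <- rotate_marker(recording$markers[[paste0("toe", sfx(side))]], R)
  n <- n_frames(recording)
  for (j in 1:2) sac[, j] <- lowpass(sac[, j], rate, filter_cutoff)
  toe_i[, 3] <- lowpass(toe_i[, 3], rate, filter_cutoff)

  have_contra <- length(events[[other]]$contacts) >= 1 ||
    length(events[[other]]$toeoffs) >= 1
  stance_i <- .stance_indicator(events[[side]]$contacts, events[[side]]$toeoffs, n)
  stance_c <- if (have_contra)
    .stance_indicator(events[[other]]$contacts, events[[other]]$toeoffs, n)
  else rep(NA, n)

  res <- lapply(seq_len(nrow(cycles)), function(i) {
    a <- cycles[i, 1]; b <- cycles[i, 2]
    idx <- a:(b - 1)
    dur <- (b - a) / rate
    path <- sum(sqrt(diff(sac[a:b, 1])^2 + diff(sac[a:b, 2])^2))
    velocity <- path / dur

    contacts_here <- c(a, events[[other]]$contacts[events[[other]]$contacts > a &
                                                     events[[other]]$contacts < b])
    lead <- c(side, rep(other, length(contacts_here) - 1))
    steps <- vapply(seq_along(contacts_here), function(k) {
      f <- contacts_here[k]
      if (lead[k] == side) heel_i[f, 1] - heel_c[f, 1] else heel_c[f, 1] - heel_i[f, 1]
    }, numeric(1))
    widths <- vapply(contacts_here, function(f) abs(heel_i[f, 2] - heel_c[f, 2]),
                     numeric(1))
    step_length <- mean(pmax(steps, 0))
    step_width <- mean(widths)

    ds <- if (have_contra) {
      both <- stance_i[idx] & stance_c[idx]
      100 * mean(both, na.rm = TRUE)
    } else NA_real_

    to <- events[[side]]$toeoffs
    to <- to[to > a & to < b]
    clearance <- if (length(to) == 1) {
      stance_z <- toe_i[a:(to - 1), 3]
      flat <- stance_z[stance_z <= min(stance_z) + 0.01]
      max(toe_i[to:(b - 1), 3]) - mean(flat)
    } else NA_real_

    data.frame(cycle = i, gait_velocity = velocity, step_length = step_length,
               step_width = step_width, double_support = ds,
               foot_clearance = clearance)
  })
  out <- do.call(rbind, res)
  attr(out, "stride_average") <- colMeans(out[, -1, drop = FALSE], na.rm = TRUE)
  if (!have_contra)
    attr(out, "flags") <- "double support undefined: contralateral events missing"
  out
}

#' Sagittal kinematic maxima per cycle
#'
#' Per-cycle extrema of the sagittal angles: maximum hip flexion, knee
#' flexion and ankle dorsiflexion, and maximum plantarflexion as a positive
#' magnitude (`|min ankle angle|` when the minimum is negative, else 0).
#'
#' @param angles A [joint_angle_series] for one leg.
#' @param cycles Two-column matrix of half-open `[start, end)` frame
#'   intervals (e.g. from [segment_cycles()]).
#' @return Data frame with one row per cycle: `max_hip_flexion`,
#'   `max_knee_flexion`, `max_dorsiflexion`, `max_plantarflexion`.
#' @export
kinematic_maxima <- function(angles, cycles) {
  stopifnot(inherits(angles, "joint_angle_series"))
  if (is.vector(cycles)) cycles <- matrix(cycles, 1, 2)
  n <- length(angles$hip)
  if (any(cycles[, 1] < 1) || any(cycles[, 2] > n + 1) || any(cycles[, 2] <= cycles[, 1]))
    gd_domain_error("cycle intervals must lie within the angle series")
  out <- lapply(seq_len(nrow(cycles)), function(i) {
    idx <- cycles[i, 1]:(cycles[i, 2] - 1)
    amin <- min(angles$ankle[idx])
    data.frame(cycle = i,
               max_hip_flexion = max(angles$hip[idx]),
               max_knee_flexion = max(angles$knee[idx]),
               max_dorsiflexion = max(angles$ankle[idx]),
               max_plantarflexion = if (amin < 0) -amin else 0)
  })
  do.call(rbind, out)
}
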