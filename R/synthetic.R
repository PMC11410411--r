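# Synthetic gait generator: seeded, ground-truth-annotated walking trials
# emulating a foot-drop cohort recorded at 100 Hz under four orthotic
# conditions (no assistance, AFO, dorsiflexion-assist harness, full-assist
# harness). Joint-angle cycles are fixed low-order harmonic templates
# rescaled to requested per-cycle extrema; planar forward kinematics turns
# them into marker trajectories.

# Healthy sagittal waveform templates over cycle phase [0, 1), degrees.
# Harmonic phases were chosen so that (a) the heel is most anterior at the
# cycle boundary (foot contact), (b) the toe is most posterior at ~66% of
# the cycle (toe-off), (c) peak plantarflexion falls in pre-swing and peak
# dorsiflexion in stance/swing, and (d) the sub-threshold velocity bands of
# the three joints overlap the way healthy gait does, so that the
# healthy-template decomposition index sits in the 5-10% range reported for
# unimpaired walking.
.gait_template <- list(
  hip   = list(mean = 10, amp = 20,        phase = 0.93),
  knee  = list(mean = 25, amp = c(20, 14), phase = c(0.80, 0.72)),
  ankle = list(mean = -2, amp = c(8, 8),   phase = c(0.36, 0.64))
)

.gd_conditions <- c("no_assistance", "afo", "newgait_dorsiflexion", "newgait_full")

.harmonic_sum <- function(phi, tpl) {
  y <- rep(tpl$mean, length(phi))
  for (k in seq_along(tpl$amp))
    y <- y + tpl$amp[k] * cos(2 * pi * k * (phi - tpl$phase[k]))
  y
}

# Joint-pair decomposition targets t satisfy t[pair] ~ f[a] + f[b] when the
# per-joint pause windows are phase-disjoint; invert the 3x3 system.
.pairs_to_joints <- function(t) {
  f <- c(hip   = (t[["hip_knee"]] + t[["hip_ankle"]] - t[["knee_ankle"]]) / 2,
         knee  = (t[["hip_knee"]] + t[["knee_ankle"]] - t[["hip_ankle"]]) / 2,
         ankle = (t[["hip_ankle"]] + t[["knee_ankle"]] - t[["hip_knee"]]) / 2)
  pmax(f, 0)
}

# Foot-sole height profile: 0 through stance, smooth bump peaking at
# `clearance` in mid-swing (phase 0.66-0.99).
.sole_profile <- function(phase, clearance) {
  d <- numeric(length(phase))
  sw <- phase > 0.66 & phase < 0.99
  d[sw] <- clearance * sin(pi * (phase[sw] - 0.66) / 0.33)^2
  d
}

#' Joint-angle series container
#'
#' Sagittal hip, knee and ankle angles (degrees) for one leg, sampled at
#' `sample_rate`. Sign convention: hip flexion +, knee flexion +, ankle
#' dorsiflexion +, plantarflexion -.
#'
#' @param hip,knee,ankle Numeric vectors of equal length, degrees.
#' @param sample_rate Sampling rate, Hz.
#' @param side Optional side label (`"left"`/`"right"`).
#' @return Object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(hip, knee, ankle, sample_rate, side = NA_character_) {
  n <- length(hip)
  if (length(knee) != n || length(ankle) != n)
    gd_domain_error("hip, knee and ankle series must have equal length")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    gd_config_error("sample_rate must be positive")
  if (any(abs(c(hip, knee, ankle)) > 180, na.rm = TRUE))
    gd_domain_error("joint angles must lie within [-180, 180] degrees")
  structure(list(hip = hip, knee = knee, ankle = ankle,
                 sample_rate = sample_rate, side = side),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d samples @ %g Hz%s\n",
              length(x$hip), x$sample_rate,
              if (is.na(x$side)) "" else paste0(" (", x$side, ")")))
  for (j in c("hip", "knee", "ankle"))
    cat(sprintf("  %-5s range [%.1f, %.1f] deg\n", j, min(x[[j]]), max(x[[j]])))
  invisible(x)
}

#' Generate one synthetic gait cycle of joint angles
#'
#' Evaluates the fixed physiologic waveform templates over one cycle and
#' rescales them so that the per-cycle extrema equal the requested maxima
#' exactly on the sampled grid. Hip and knee templates are scaled
#' multiplicatively (their maxima are the targets); the ankle template is
#' rescaled affinely so its maximum equals `dorsiflexion` and its minimum
#' equals `-plantarflexion`.
#'
#' The cycle is sampled on the half-open phase grid `[0, 1)` so that
#' consecutive cycles tile seamlessly; the underlying template is periodic
#' (its value at phase 0 and phase 1 is identical).
#'
#' @param joint_maxima Named numeric vector with entries `hip`, `knee`,
#'   `dorsiflexion`, `plantarflexion` (degrees; plantarflexion as a positive
#'   magnitude). Missing entries default to the healthy minima
#'   `c(hip = 30, knee = 60, dorsiflexion = 15, plantarflexion = 20)`.
#' @param cycle_duration Cycle duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param side Optional side label carried on the result.
#' @return A [joint_angle_series] with `round(cycle_duration * sample_rate)`
#'   samples.
#' @export
generate_angle_cycle <- function(joint_maxima = c(hip = 30, knee = 60,
                                                  dorsiflexion = 15,
                                                  plantarflexion = 20),
                                 cycle_duration = 1.2, sample_rate = 100,
                                 side = NA_character_) {
  defaults <- c(hip = 30, knee = 60, dorsiflexion = 15, plantarflexion = 20)
  jm <- defaults
  jm[names(joint_maxima)] <- joint_maxima
  if (any(!is.finite(jm))) gd_config_error("joint maxima must be finite")
  if (jm[["dorsiflexion"]] < 0 || jm[["plantarflexion"]] < 0)
    gd_config_error("dorsiflexion and plantarflexion maxima must be >= 0")
  if (jm[["hip"]] < 0 || jm[["knee"]] < 0)
    gd_config_error("hip and knee flexion maxima must be >= 0")
  if (!is.numeric(cycle_duration) || cycle_duration <= 0)
    gd_config_error("cycle_duration must be positive")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    gd_config_error("sample_rate must be positive")
  n <- round(cycle_duration * sample_rate)
  if (n < 8) gd_config_error("cycle must span at least 8 samples")
  phi <- (seq_len(n) - 1) / n

  hip_raw  <- .harmonic_sum(phi, .gait_template$hip)
  knee_raw <- .harmonic_sum(phi, .gait_template$knee)
  ank_raw  <- .harmonic_sum(phi, .gait_template$ankle)

  hip  <- hip_raw  * (jm[["hip"]]  / max(hip_raw))
  knee <- knee_raw * (jm[["knee"]] / max(knee_raw))
  span <- max(ank_raw) - min(ank_raw)
  a <- (jm[["dorsiflexion"]] + jm[["plantarflexion"]]) / span
  b <- jm[["dorsiflexion"]] - a * max(ank_raw)
  ankle <- a * ank_raw + b

  joint_angle_series(hip, knee, ankle, sample_rate, side = side)
}

#' Freeze one joint for a fraction of the cycle
#'
#' Holds the named joint's angle constant over a window of
#' `round(fraction * n)` samples and uniformly time-warps the remainder of
#' the cycle so that the cycle duration and the periodic continuation are
#' preserved. The generator-side inverse of pause detection: downstream, the
#' decomposition stage should recover `fraction` as paused time.
#'
#' @param series A [joint_angle_series] spanning one cycle.
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @param fraction Fraction of the cycle to pause, in `[0, 1]`.
#' @param placement Cycle-phase offset of the pause window start, in `[0, 1)`.
#' @return The series with the joint's channel warped; other channels
#'   untouched.
#' @export
inject_pause <- function(series, joint, fraction, placement = 0.25) {
  stopifnot(inherits(series, "joint_angle_series"))
  if (!joint %in% c("hip", "knee", "ankle"))
    gd_domain_error(sprintf("unknown joint '%s'", joint))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    gd_domain_error("pause fraction must lie in [0, 1]")
  x <- series[[joint]]
  n <- length(x)
  m <- round(fraction * n)
  if (m == 0) return(series)
  s0 <- round((placement %% 1) * n)
  if (m >= n) {
    series[[joint]] <- rep(x[s0 + 1], n)
    return(series)
  }
  pos <- 0:(n - 1)
  in_pause <- ((pos - s0) %% n) < m
  adv <- n / (n - m)
  # phase advanced by `adv` per preceding non-paused sample
  k_before <- c(0, cumsum(!in_pause)[-n])
  ph <- (adv * k_before) %% n
  i0 <- floor(ph)
  w <- ph - i0
  series[[joint]] <- x[i0 + 1] * (1 - w) + x[(i0 + 1) %% n + 1] * w
  series
}

#' Planar forward kinematics: joint angles to marker trajectories
#'
#' Advances the pelvis along +X at `pelvis_speed` and places hip, knee,
#' ankle, heel and toe markers from the sagittal joint angles and segment
#' lengths. The mediolateral (Y) position of the leg is fixed at
#' `lateral_offset` (left +). Vertically, the whole leg chain is translated
#' per frame so that the foot-sole minimum (lower of heel and toe) follows
#' `sole_height` (ground level 0 by default); per-frame translation leaves
#' every segment vector, and hence every derived joint angle, untouched.
#'
#' @param series A [joint_angle_series] (any length; tiled cycles welcome).
#' @param segment_lengths Named list/vector with `thigh`, `shank`, `heel`,
#'   `toe` lengths in meters (`heel`/`toe` are the horizontal foot distances
#'   from the ankle to the heel and toe markers).
#' @param pelvis_speed Forward speed of the pelvis, m/s.
#' @param side `"left"` or `"right"` (marker name suffix `_L`/`_R`).
#' @param lateral_offset Y offset of the leg, meters (left positive).
#' @param pelvis_height Sacrum height, meters.
#' @param sole_height Optional numeric vector (length of the series): target
#'   height of the foot-sole minimum per frame. `NULL` grounds the sole at
#'   its global minimum.
#' @param start_x Initial pelvis X, meters.
#' @return A [trial_recording] holding `sacrum` plus the five per-side
#'   markers for this leg.
#' @export
angles_to_markers <- function(series, segment_lengths = gd_segment_lengths(),
                              pelvis_speed = 0.65, side = "left",
                              lateral_offset = 0.1, pelvis_height = 0.95,
                              sole_height = NULL, start_x = 0) {
  stopifnot(inherits(series, "joint_angle_series"))
  seg <- as.list(segment_lengths)
  needed <- c("thigh", "shank", "heel", "toe")
  if (!all(needed %in% names(seg)) || any(unlist(seg[needed]) <= 0))
    gd_config_error("segment_lengths must contain positive thigh, shank, heel, toe")
  side <- match.arg(side, c("left", "right"))
  n <- length(series$hip)
  t <- (seq_len(n) - 1) / series$sample_rate

  ch <- .leg_chain(series, seg, pelvis_speed, lateral_offset, pelvis_height,
                   sole_height, start_x)
  suffix <- if (side == "left") "_L" else "_R"
  markers <- c(list(sacrum = ch$sacrum), setNames(ch$leg, paste0(names(ch$leg), suffix)))
  trial_recording(markers = markers, sample_rate = series$sample_rate,
                  participant_id = "synthetic", condition = "none",
                  paretic_side = side)
}

# One leg's marker chain. Returns sacrum (midline) and hip/knee/ankle/heel/
# toe Nx3 matrices.
.leg_chain <- function(series, seg, speed, y_off, pelvis_h, sole_height, start_x) {
  n <- length(series$hip)
  t <- (seq_len(n) - 1) / series$sample_rate
  h <- series$hip * pi / 180
  k <- series$knee * pi / 180
  a <- series$ankle * pi / 180
  th_s <- h - k          # shank inclination from vertical
  pitch <- th_s + a      # foot pitch from horizontal (toe-up +)

  sac_x <- start_x + speed * t
  hip_x <- sac_x
  hip_z <- rep(pelvis_h, n)
  knee_x <- hip_x + seg$thigh * sin(h)
  knee_z <- hip_z - seg$thigh * cos(h)
  ank_x <- knee_x + seg$shank * sin(th_s)
  ank_z <- knee_z - seg$shank * cos(th_s)
  heel_x <- ank_x - seg$heel * cos(pitch)
  heel_z <- ank_z - seg$heel * sin(pitch) - 0.05
  toe_x <- ank_x + seg$toe * cos(pitch)
  toe_z <- ank_z + seg$toe * sin(pitch) - 0.05

  sole <- pmin(heel_z, toe_z)
  delta <- if (is.null(sole_height)) rep(-min(sole), n) else sole_height - sole
  mk <- function(x, z, shift = TRUE)
    cbind(X = x, Y = rep(y_off, n), Z = if (shift) z + delta else z)
  list(
    sacrum = cbind(X = sac_x, Y = rep(0, n), Z = rep(pelvis_h, n)),
    leg = list(hip = mk(hip_x, hip_z), knee = mk(knee_x, knee_z),
               ankle = mk(ank_x, ank_z), heel = mk(heel_x, heel_z),
               toe = mk(toe_x, toe_z))
  )
}

#' Default segment lengths (meters)
#' @return Named list with thigh, shank, heel and toe lengths.
#' @export
gd_segment_lengths <- function() list(thigh = 0.42, shank = 0.43, heel = 0.07, toe = 0.18)

#' Synthetic cohort configuration
#'
#' Assembles and validates the parameters of the synthetic study cohort. The
#' defaults emulate the reference foot-drop population: 16 participants,
#' 100 Hz capture, gait speed 0.65 +/- 0.25 m/s with condition-dependent
#' speed gains, four walking conditions, per-condition sagittal range-of-
#' motion means/SDs, foot clearance, and joint-pair pause targets; three
#' trials of four strides per condition.
#'
#' @param n_participants Number of participants.
#' @param n_trials_per_condition Trials per condition per participant.
#' @param strides_per_trial Complete strides (gait cycles) per trial.
#' @param sample_rate Capture rate, Hz.
#' @param conditions Ordered condition labels.
#' @param speed_mean,speed_sd Baseline self-selected gait speed, m/s.
#' @param speed_shift Named per-condition additive speed effect, m/s.
#' @param rom_means,rom_sds Condition x joint matrices (rows = conditions,
#'   columns `hip`, `knee`, `plantarflexion`, `dorsiflexion`), degrees.
#' @param healthy_maxima Non-paretic-side joint maxima, degrees.
#' @param clearance_mean,clearance_sd Named per-condition swing foot (peak
#'   toe height) clearance, m.
#' @param pause_fractions,pause_sds Pair x condition matrices (rows
#'   `hip_knee`, `hip_ankle`, `knee_ankle`) of target decomposition
#'   fractions in `[0, 1]`.
#' @param step_length_mean,step_length_sd Step length distribution, m.
#' @param step_width_mean,step_width_sd Step width distribution, m.
#' @param noise_sd_marker Additive i.i.d. Gaussian marker noise SD, m.
#' @param noise_sd_angle Additive stride-level joint-angle noise SD, degrees.
#' @param segment_lengths See [gd_segment_lengths()].
#' @param pelvis_height Sacrum height, m.
#' @param seed Master seed; one RNG stream per participant is derived from
#'   it, so cohorts are reproducible participant-by-participant.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_participants = 16,
                             n_trials_per_condition = 3,
                             strides_per_trial = 4,
                             sample_rate = 100,
                             conditions = .gd_conditions,
                             speed_mean = 0.65, speed_sd = 0.25,
                             speed_shift = c(no_assistance = 0, afo = 0.06,
                                             newgait_dorsiflexion = 0.07,
                                             newgait_full = 0.12),
                             rom_means = NULL, rom_sds = NULL,
                             healthy_maxima = c(hip = 30, knee = 60,
                                                dorsiflexion = 15,
                                                plantarflexion = 20),
                             clearance_mean = c(no_assistance = 0.16, afo = 0.18,
                                                newgait_dorsiflexion = 0.18,
                                                newgait_full = 0.19),
                             clearance_sd = c(no_assistance = 0.05, afo = 0.03,
                                              newgait_dorsiflexion = 0.04,
                                              newgait_full = 0.02),
                             pause_fractions = NULL, pause_sds = NULL,
                             step_length_mean = 0.50, step_length_sd = 0.09,
                             step_width_mean = 0.21, step_width_sd = 0.06,
                             noise_sd_marker = 0.002, noise_sd_angle = 0.5,
                             segment_lengths = gd_segment_lengths(),
                             pelvis_height = 0.95,
                             seed = 1L) {
  joints <- c("hip", "knee", "plantarflexion", "dorsiflexion")
  if (is.null(rom_means))
    rom_means <- matrix(c(26.8, 35.7, 24.6,  9.6,
                          29.0, 37.0, 19.5, 14.5,
                          28.5, 39.5, 26.5, 14.3,
                          27.5, 36.2, 28.0, 12.0),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(.gd_conditions, joints))
  if (is.null(rom_sds))
    rom_sds <- matrix(c(7.8, 12.8, 4.21, 4.21,
                        10.2, 10.6, 4.29, 3.29,
                        8.2,  5.16, 7.23, 5.20,
                        6.9,  7.28, 6.31, 6.88),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(.gd_conditions, joints))
  pairs <- c("hip_knee", "hip_ankle", "knee_ankle")
  if (is.null(pause_fractions))
    pause_fractions <- matrix(c(0.161, 0.217, 0.115, 0.108,
                                0.137, 0.202, 0.122, 0.147,
                                0.217, 0.258, 0.151, 0.184),
                              nrow = 3, byrow = TRUE,
                              dimnames = list(pairs, .gd_conditions))
  if (is.null(pause_sds))
    pause_sds <- matrix(c(0.0281, 0.0202, 0.0682, 0.0563,
                          0.0109, 0.0293, 0.0406, 0.0532,
                          0.0451, 0.0584, 0.0405, 0.0343),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(pairs, .gd_conditions))

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    strides_per_trial = as.integer(strides_per_trial),
    sample_rate = sample_rate, conditions = conditions,
    speed_mean = speed_mean, speed_sd = speed_sd, speed_shift = speed_shift,
    rom_means = rom_means, rom_sds = rom_sds, healthy_maxima = healthy_maxima,
    clearance_mean = clearance_mean, clearance_sd = clearance_sd,
    pause_fractions = pause_fractions, pause_sds = pause_sds,
    step_length_mean = step_length_mean, step_length_sd = step_length_sd,
    step_width_mean = step_width_mean, step_width_sd = step_width_sd,
    noise_sd_marker = noise_sd_marker, noise_sd_angle = noise_sd_angle,
    segment_lengths = segment_lengths, pelvis_height = pelvis_height,
    seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_participants < 1 || n_trials_per_condition < 1 || strides_per_trial < 1)
      gd_config_error("participant, trial and stride counts must be >= 1")
    if (sample_rate <= 0) gd_config_error("sample_rate must be positive")
    if (speed_sd < 0) gd_config_error("speed_sd must be >= 0")
    if (length(conditions) < 1 || anyDuplicated(conditions))
      gd_config_error("conditions must be non-empty and unique")
    if (!all(conditions %in% rownames(rom_means)))
      gd_config_error("rom_means must have one row per condition")
    if (any(pause_fractions < 0 | pause_fractions > 1))
      gd_config_error("pause_fractions must lie in [0, 1]")
    if (noise_sd_marker < 0 || noise_sd_angle < 0)
      gd_config_error("noise SDs must be >= 0")
  })
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d participants x %d conditions x %d trials (%d strides, %g Hz), seed %d\n",
              x$n_participants, length(x$conditions), x$n_trials_per_condition,
              x$strides_per_trial, x$sample_rate, x$seed))
  invisible(x)
}

#' Generate a synthetic walking cohort with ground truth
#'
#' Draws per-participant gait parameters once from participant-specific RNG
#' streams (derived from the master seed), applies the configured
#' per-condition effects (speed gain, range-of-motion, clearance, joint-pair
#' pause structure), and synthesizes every trial as tiled angle cycles passed
#' through planar forward kinematics plus additive marker noise. The paretic
#' side receives the impaired per-condition maxima and injected joint pauses;
#' the contralateral side walks with the healthy template.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `gait_cohort` with elements `trials` (list of
#'   [trial_recording]) and `truth` (list of per-trial ground-truth records:
#'   event frames, cycle intervals, true speed, per-cycle joint maxima,
#'   injected pause fractions, clearance).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  config <- validate_synthetic_config(config)
  seeds <- derive_seeds(config$seed, config$n_participants)
  trials <- list()
  truth <- list()
  for (p in seq_len(config$n_participants)) {
    res <- .generate_participant(config, p, seeds[p])
    trials <- c(trials, res$trials)
    truth <- c(truth, res$truth)
  }
  structure(list(trials = trials, truth = truth, config = config),
            class = "gait_cohort")
}

.generate_participant <- function(cfg, p, seed_p) {
  set.seed(seed_p)
  pid <- sprintf("P%02d", p)
  z <- list(speed = rnorm(1), hip = rnorm(1), knee = rnorm(1),
            dorsi = rnorm(1), plantar = rnorm(1), clear = rnorm(1),
            step = rnorm(1), width = rnorm(1),
            pairs = rnorm(3))
  paretic <- if (runif(1) < 10 / 16) "left" else "right"
  stride_len <- 2 * max(0.25, cfg$step_length_mean + z$step * cfg$step_length_sd)
  step_width <- max(0.08, cfg$step_width_mean + z$width * cfg$step_width_sd)

  trials <- list()
  truth <- list()
  for (cond in cfg$conditions) {
    rom <- cfg$rom_means[cond, ]
    rsd <- cfg$rom_sds[cond, ]
    maxima <- c(hip = max(5, rom[["hip"]] + z$hip * rsd[["hip"]]),
                knee = max(10, rom[["knee"]] + z$knee * rsd[["knee"]]),
                dorsiflexion = max(0, rom[["dorsiflexion"]] + z$dorsi * rsd[["dorsiflexion"]]),
                plantarflexion = max(0, rom[["plantarflexion"]] + z$plantar * rsd[["plantarflexion"]]))
    speed_pc <- max(0.2, cfg$speed_mean + (cfg$speed_shift[cond] %||% 0) +
                      z$speed * cfg$speed_sd)
    clearance <- max(0.05, cfg$clearance_mean[[cond]] + z$clear * cfg$clearance_sd[[cond]])
    pair_target <- pmin(pmax(cfg$pause_fractions[, cond] +
                               z$pairs * cfg$pause_sds[, cond], 0), 0.45)
    joint_frac <- .pairs_to_joints(as.list(pair_target))

    for (tr in seq_len(cfg$n_trials_per_condition)) {
      speed_t <- max(0.2, speed_pc + rnorm(1, 0, 0.02))
      out <- .generate_trial(cfg, pid, cond, tr, paretic, maxima, speed_t,
                             stride_len, step_width, clearance, joint_frac,
                             pair_target)
      trials[[length(trials) + 1]] <- out$recording
      truth[[length(truth) + 1]] <- out$truth
    }
  }
  list(trials = trials, truth = truth)
}

# Pause window placements per joint (cycle phase), chosen disjoint so pair
# indices add up; windows stay disjoint for joint fractions up to 0.15.
.pause_placement <- c(hip = 0.05, knee = 0.30, ankle = 0.75)

.generate_trial <- function(cfg, pid, cond, tr, paretic, maxima, speed,
                            stride_len, step_width, clearance, joint_frac,
                            pair_target) {
  rate <- cfg$sample_rate
  Tn <- round(stride_len / speed * rate)        # frames per cycle
  n_total <- round((cfg$strides_per_trial + 1.6) * Tn)

  cyc_par <- generate_angle_cycle(maxima, Tn / rate, rate, side = paretic)
  for (j in names(joint_frac)) if (joint_frac[[j]] > 0)
    cyc_par <- inject_pause(cyc_par, j, joint_frac[[j]], .pause_placement[[j]])
  cyc_healthy <- generate_angle_cycle(cfg$healthy_maxima, Tn / rate, rate)

  other <- if (paretic == "left") "right" else "left"
  phase_off <- c(left = 0.70, right = 0.20)
  sides <- list()
  sides[[paretic]] <- .tile_side(cyc_par, Tn, n_total, phase_off[[paretic]], cfg)
  sides[[other]] <- .tile_side(cyc_healthy, Tn, n_total, phase_off[[other]], cfg)

  markers <- list()
  clear_side <- c(left = NA_real_, right = NA_real_)
  clear_side[paretic] <- clearance
  clear_side[other] <- 0.18
  for (s in c("left", "right")) {
    y <- (if (s == "left") 1 else -1) * step_width / 2
    d <- .sole_profile(sides[[s]]$phase, clear_side[[s]])
    ch <- .leg_chain(sides[[s]]$angles, as.list(cfg$segment_lengths), speed, y,
                     cfg$pelvis_height, d, start_x = 0)
    suffix <- if (s == "left") "_L" else "_R"
    markers[["sacrum"]] <- ch$sacrum
    markers <- c(markers, setNames(ch$leg, paste0(names(ch$leg), suffix)))
  }

  clean <- trial_recording(markers = markers, sample_rate = rate,
                           participant_id = pid, condition = cond,
                           paretic_side = paretic)
  ev <- detect_events(clean)
  cyc_int <- segment_cycles(ev, paretic)
  ang_par <- sides[[paretic]]$angles
  max_per_cycle <- NULL
  if (nrow(cyc_int) > 0) {
    max_per_cycle <- do.call(rbind, lapply(seq_len(nrow(cyc_int)), function(i) {
      idx <- cyc_int[i, 1]:(cyc_int[i, 2] - 1)
      c(hip = max(ang_par$hip[idx]), knee = max(ang_par$knee[idx]),
        dorsiflexion = max(ang_par$ankle[idx]),
        plantarflexion = max(0, -min(ang_par$ankle[idx])))
    }))
  }

  if (cfg$noise_sd_marker > 0)
    for (nm in names(markers))
      markers[[nm]] <- markers[[nm]] +
        matrix(rnorm(length(markers[[nm]]), 0, cfg$noise_sd_marker),
               ncol = 3, dimnames = dimnames(markers[[nm]]))

  recording <- trial_recording(markers = markers, sample_rate = rate,
                               participant_id = pid, condition = cond,
                               paretic_side = paretic, trial = tr)
  truth <- list(
    participant_id = pid, condition = cond, trial = tr, paretic_side = paretic,
    speed = speed, cycle_frames = Tn,
    events = list(left = list(contacts = ev$left$contacts, toeoffs = ev$left$toeoffs),
                  right = list(contacts = ev$right$contacts, toeoffs = ev$right$toeoffs)),
    cycles = cyc_int,
    joint_maxima = max_per_cycle, requested_maxima = maxima,
    pause_joint = joint_frac, pause_pairs = pair_target,
    clearance = clearance, stride_length = stride_len, step_width = step_width)
  list(recording = recording, truth = truth)
}

# Tile one template cycle across the trial with a per-side phase offset and
# optional stride-level angle noise (smooth, added as a per-cycle offset).
.tile_side <- function(cycle, Tn, n_total, offset, cfg) {
  idx0 <- (0:(n_total - 1) + round(offset * Tn)) %% Tn
  ang <- list(hip = cycle$hip[idx0 + 1], knee = cycle$knee[idx0 + 1],
              ankle = cycle$ankle[idx0 + 1])
  if (cfg$noise_sd_angle > 0) {
    cyc_id <- ((0:(n_total - 1) + round(offset * Tn)) %/% Tn) + 1
    for (j in names(ang)) {
      off <- rnorm(max(cyc_id), 0, cfg$noise_sd_angle)
      ang[[j]] <- ang[[j]] + off[cyc_id]
    }
  }
  list(angles = joint_angle_series(ang$hip, ang$knee, ang$ankle, cfg$sample_rate),
       phase = idx0 / Tn)
}

#' Simulate comfort ratings for the assisted conditions
#'
#' Draws per-participant visual-analog comfort scores (0 = very comfortable,
#' 10 = very uncomfortable) for the three assisted walking conditions, with
#' a shared participant disposition plus condition-specific scatter,
#' truncated to the scale.
#'
#' @param n_participants Number of participants.
#' @param means,sds Named per-condition score means and SDs.
#' @param seed RNG seed.
#' @return Data frame with `participant_id` and one column per condition.
#' @export
generate_comfort_scores <- function(n_participants = 16,
                                    means = c(afo = 4.3,
                                              newgait_dorsiflexion = 4.5,
                                              newgait_full = 4.4),
                                    sds = c(afo = 2.9,
                                            newgait_dorsiflexion = 2.3,
                                            newgait_full = 2.3),
                                    seed = 1L) {
  set.seed(seed)
  base <- rnorm(n_participants)   # participant disposition, shared across devices
  out <- data.frame(participant_id = sprintf("P%02d", seq_len(n_participants)))
  for (cond in names(means)) {
    raw <- means[[cond]] + sds[[cond]] * (0.8 * base + 0.6 * rnorm(n_participants))
    out[[cond]] <- pmin(10, pmax(0, raw))
  }
  out
}
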