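# Shared fixtures, built in code at test time.

# Small noise-free cohort configuration for recovery tests.
noise_free_config <- function(n = 2, seed = 101, ...) {
  synthetic_config(n_participants = n, noise_sd_marker = 0, noise_sd_angle = 0,
                   seed = seed, ...)
}

# One-cycle pair of "linear sweep" channels: every joint moves at constant
# angular velocity, so no natural sub-threshold pause bands exist and an
# injected pause is the only paused episode.
sweep_cycle <- function(n = 120, rate = 100, amplitude = 50) {
  ramp <- seq(0, amplitude, length.out = n)
  joint_angle_series(hip = ramp, knee = ramp, ankle = ramp - amplitude / 2,
                     sample_rate = rate)
}

# Sinusoidal series over one cycle (n samples, half-open phase grid).
sine_series <- function(n = 120, rate = 100, amplitude = 30, phase = 0) {
  phi <- (seq_len(n) - 1) / n
  amplitude * sin(2 * pi * (phi + phase))
}

# Direct per-frame enumeration oracle for the decomposition index.
brute_force_index <- function(a, b) {
  one <- 0L
  both <- 0L
  for (i in seq_along(a)) {
    if (a[i] && b[i]) both <- both + 1L
    else if (a[i] || b[i]) one <- one + 1L
  }
  denom <- length(a) - both
  if (denom == 0) 0 else 100 * one / denom
}

# A simple standing recording: both legs vertical, feet flat, pelvis either
# static or advancing at `speed`; used for neutral-pose angle checks.
standing_recording <- function(n = 200, rate = 100, speed = 0,
                               ankle_pitch_deg = 0) {
  t <- (seq_len(n) - 1) / rate
  seg <- gd_segment_lengths()
  x0 <- speed * t
  p <- ankle_pitch_deg * pi / 180
  mk <- function(x, y, z) cbind(X = x, Y = rep(y, n), Z = rep(z, n))
  leg <- function(y) {
    hz <- 0.95
    kz <- hz - seg$thigh
    az <- kz - seg$shank
    list(hip = mk(x0, y, hz), knee = mk(x0, y, kz), ankle = mk(x0, y, az),
         heel = mk(x0 - seg$heel * cos(p), y, az - seg$heel * sin(p) + 0.02),
         toe = mk(x0 + seg$toe * cos(p), y, az + seg$toe * sin(p) + 0.02))
  }
  L <- leg(0.1)
  R <- leg(-0.1)
  markers <- c(list(sacrum = mk(x0, 0, 0.95)),
               setNames(L, paste0(names(L), "_L")),
               setNames(R, paste0(names(R), "_R")))
  trial_recording(markers, rate, participant_id = "fix", condition = "none")
}

# Cached default-config cohorts keyed by argument signature, so expensive
# generation runs once per test session.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(cfg) {
  key <- paste0("c", cfg$n_participants, "s", cfg$seed, "m", cfg$noise_sd_marker,
                "a", cfg$noise_sd_angle)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cfg)
  .cohort_cache[[key]]
}

# Writer that skips validation, for constructing deliberately damaged files.
write_trial_unchecked <- function(rec, path) gaitdecomp:::.write_trial_csv(rec, path)
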