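test_that("generated cycle extrema match the requested joint maxima", {
  s <- generate_angle_cycle(c(hip = 30, knee = 60, dorsiflexion = 15,
                              plantarflexion = 20),
                            cycle_duration = 1.2, sample_rate = 100)
  expect_length(s$hip, 120)
  expect_equal(max(s$hip), 30, tolerance = 0.1 / 30)
  expect_equal(max(s$knee), 60, tolerance = 0.1 / 60)
  expect_equal(max(s$ankle), 15, tolerance = 0.1 / 15)
  expect_equal(min(s$ankle), -20, tolerance = 0.1 / 20)

  # impaired ankle values: dorsiflexion 9.6, plantarflexion 24.6
  s2 <- generate_angle_cycle(c(dorsiflexion = 9.6, plantarflexion = 24.6))
  expect_equal(max(s2$ankle), 9.6, tolerance = 1e-9)
  expect_equal(min(s2$ankle), -24.6, tolerance = 1e-9)
})

test_that("zero maxima give a constant zero cycle", {
  s <- generate_angle_cycle(c(hip = 0, knee = 0, dorsiflexion = 0,
                              plantarflexion = 0))
  expect_true(all(abs(c(s$hip, s$knee, s$ankle)) < 1e-12))
})

test_that("the cycle is periodic: tiling introduces no discontinuity", {
  s <- generate_angle_cycle(cycle_duration = 1.5, sample_rate = 100)
  for (j in c("hip", "knee", "ankle")) {
    x <- s[[j]]
    wrap_step <- abs(x[1] - x[length(x)])
    expect_lte(wrap_step, max(abs(diff(x))) * 1.5)
  }
  # the underlying template itself is exactly periodic over the cycle
  phi_ends <- c(0, 1)
  for (tpl in gaitdecomp:::.gait_template) {
    v <- gaitdecomp:::.harmonic_sum(phi_ends, tpl)
    expect_equal(v[1], v[2], tolerance = 1e-9)
  }
})

test_that("invalid cycle parameters are rejected as configuration errors", {
  expect_error(generate_angle_cycle(cycle_duration = 0),
               class = "gaitdecomp_config_error")
  expect_error(generate_angle_cycle(sample_rate = -1),
               class = "gaitdecomp_config_error")
  expect_error(generate_angle_cycle(c(dorsiflexion = -3)),
               class = "gaitdecomp_config_error")
})

test_that("inject_pause freezes the joint and preserves the cycle", {
  s <- generate_angle_cycle()
  expect_identical(inject_pause(s, "knee", 0), s)

  full <- inject_pause(s, "knee", 1)
  expect_true(all(diff(full$knee) == 0))
  expect_length(full$knee, length(s$knee))

  f <- 0.2
  p <- inject_pause(s, "knee", f, placement = 0.3)
  n <- length(s$knee)
  expect_length(p$knee, n)
  expect_identical(p$hip, s$hip)
  expect_identical(p$ankle, s$ankle)
  # exactly round(f*n) zero-velocity steps inside the pause window
  expect_equal(sum(diff(p$knee) == 0), round(f * n) - 1 + 1, tolerance = 0)
  # the warped channel still covers the original range (time-warp, not clip)
  expect_equal(range(p$knee), range(s$knee), tolerance = 0.05)

  expect_error(inject_pause(s, "knee", 1.2), class = "gaitdecomp_domain_error")
  expect_error(inject_pause(s, "spine", 0.1), class = "gaitdecomp_domain_error")
})

test_that("injected pause fraction is recovered by velocity thresholding", {
  s <- sweep_cycle()
  p <- inject_pause(s, "knee", 0.2, placement = 0.3)
  v <- angular_velocity(p$knee, 100, filter_cutoff = NULL)
  m <- pause_mask(v)
  expect_lt(abs(mean(m$mask) - 0.2), 0.02)   # within 2 frames of the window
  # downstream: decomposition of (paused knee, moving hip) reads ~20%
  vh <- angular_velocity(p$hip, 100, filter_cutoff = NULL)
  D <- decomposition_index(pause_mask(vh), m)
  expect_equal(D, 20, tolerance = 1.5)
})

test_that("forward kinematics obey speed, geometry and angle consistency", {
  s <- generate_angle_cycle(cycle_duration = 1.2)
  # static: zero speed and constant angles freeze every marker
  const <- joint_angle_series(rep(10, 100), rep(15, 100), rep(-5, 100), 100)
  rec0 <- angles_to_markers(const, pelvis_speed = 0)
  for (m in rec0$markers) expect_lt(max(apply(m, 2, function(x) diff(range(x)))), 1e-12)

  # pelvis displacement = speed x time
  long <- joint_angle_series(rep(s$hip, 9)[1:1000], rep(s$knee, 9)[1:1000],
                             rep(s$ankle, 9)[1:1000], 100)
  rec <- angles_to_markers(long, pelvis_speed = 0.65)
  dx <- rec$markers$sacrum[1000, 1] - rec$markers$sacrum[1, 1]
  expect_equal(unname(dx), 0.65 * 9.99, tolerance = 1e-9)

  # inverse geometry: knee angle from thigh/shank marker vectors
  thigh <- rec$markers$knee_L - rec$markers$hip_L
  shank <- rec$markers$ankle_L - rec$markers$knee_L
  th_t <- atan2(thigh[, 1], -thigh[, 3])
  th_s <- atan2(shank[, 1], -shank[, 3])
  knee_rederived <- (th_t - th_s) * 180 / pi
  expect_lt(max(abs(knee_rederived - long$knee)), 0.5)
})

test_that("segment lengths must be positive", {
  s <- generate_angle_cycle()
  expect_error(angles_to_markers(s, segment_lengths = list(thigh = -1, shank = 0.4,
                                                           heel = 0.07, toe = 0.18)),
               class = "gaitdecomp_config_error")
})

test_that("cohort generation is deterministic and complete", {
  cfg <- synthetic_config(n_participants = 2, seed = 55)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  # participants x conditions x trials
  expect_length(a$trials, 2 * 4 * 3)
  conds <- vapply(a$trials, function(x) x$condition, "")
  expect_equal(sort(unique(conds)), sort(gaitdecomp:::.gd_conditions))
  # ground truth annotates every trial with increasing event frames
  for (tr in a$truth) {
    expect_true(all(diff(tr$events$left$contacts) > 0))
    expect_true(all(tr$pause_joint >= 0 & tr$pause_joint <= 1))
  }
})

test_that("the full study layout yields 192 trials", {
  co <- cached_cohort(synthetic_config(n_participants = 16, seed = 3))
  expect_length(co$trials, 192)
})

test_that("cohort seeds are participant-local: a prefix of participants is stable", {
  a <- generate_cohort(synthetic_config(n_participants = 1, seed = 77))
  b <- generate_cohort(synthetic_config(n_participants = 3, seed = 77))
  expect_identical(a$trials[[1]]$markers, b$trials[[1]]$markers)
})

test_that("generated marker set is sufficient for the whole pipeline", {
  co <- cached_cohort(noise_free_config(n = 1, seed = 9))
  rec <- co$trials[[1]]
  ev <- detect_events(rec)
  side <- rec$paretic_side
  cyc <- segment_cycles(ev, side)
  expect_gte(nrow(cyc), 1)
  st <- spatiotemporal(rec, ev)
  expect_true(all(is.finite(st$gait_velocity)))
  ang <- compute_sagittal_angles(rec)[[side]]
  km <- kinematic_maxima(ang, cyc)
  dc <- decomposition_all_pairs(ang, cyc)
  expect_true(all(is.finite(unlist(dc$trial_mean))))
  expect_true(all(is.finite(unlist(km[, -1]))))
})
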