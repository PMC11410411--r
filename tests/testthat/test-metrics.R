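test_that("neutral standing pose gives zero joint angles", {
  rec <- standing_recording()
  ang <- compute_sagittal_angles(rec)
  for (s in c("left", "right")) for (j in c("hip", "knee", "ankle"))
    expect_lt(max(abs(ang[[s]][[j]])), 1e-9)
})

test_that("a 15 degree toes-up foot reads as +15 degrees ankle", {
  rec <- standing_recording(ankle_pitch_deg = 15)
  ang <- compute_sagittal_angles(rec)
  expect_equal(ang$left$ankle, rep(15, 200), tolerance = 1e-9)
  expect_equal(ang$left$hip, rep(0, 200), tolerance = 1e-9)
})

test_that("marker-derived angles recover the generating angles within 0.5 degrees", {
  co <- cached_cohort(noise_free_config(n = 2, seed = 21))
  for (i in seq_along(co$trials)) {
    rec <- co$trials[[i]]
    tr <- co$truth[[i]]
    side <- rec$paretic_side
    ang <- compute_sagittal_angles(rec, side)[[side]]
    cyc <- tr$cycles
    km <- kinematic_maxima(ang, cyc)
    expect_lt(max(abs(km$max_hip_flexion - tr$joint_maxima[, "hip"])), 0.5)
    expect_lt(max(abs(km$max_knee_flexion - tr$joint_maxima[, "knee"])), 0.5)
    expect_lt(max(abs(km$max_dorsiflexion - tr$joint_maxima[, "dorsiflexion"])), 0.5)
    expect_lt(max(abs(km$max_plantarflexion - tr$joint_maxima[, "plantarflexion"])), 0.5)
  }
})

test_that("degenerate zero-length segments raise a data-quality error", {
  rec <- standing_recording()
  rec$markers$knee_L <- rec$markers$hip_L
  expect_error(compute_sagittal_angles(rec), regexp = "thigh",
               class = "gaitdecomp_data_error")
})

test_that("kinematic maxima handle constant and template cycles", {
  z <- joint_angle_series(rep(0, 100), rep(0, 100), rep(0, 100), 100)
  km0 <- kinematic_maxima(z, c(1, 101))
  expect_equal(unlist(km0[, -1]), c(max_hip_flexion = 0, max_knee_flexion = 0,
                                    max_dorsiflexion = 0, max_plantarflexion = 0))
  s <- generate_angle_cycle(c(hip = 30, knee = 60, dorsiflexion = 15,
                              plantarflexion = 20))
  km <- kinematic_maxima(s, c(1, length(s$hip) + 1))
  expect_equal(km$max_hip_flexion, 30, tolerance = 1e-6)
  expect_equal(km$max_knee_flexion, 60, tolerance = 1e-6)
  expect_equal(km$max_dorsiflexion, 15, tolerance = 1e-6)
  expect_equal(km$max_plantarflexion, 20, tolerance = 1e-6)
})

test_that("gait velocity recovers the generated speed within 1%", {
  co <- cached_cohort(noise_free_config(n = 2, seed = 21))
  for (i in seq_along(co$trials)) {
    rec <- co$trials[[i]]
    st <- spatiotemporal(rec, detect_events(rec))
    v <- attr(st, "stride_average")[["gait_velocity"]]
    expect_equal(v, co$truth[[i]]$speed, tolerance = 0.01)
  }
})

test_that("velocity x cycle duration matches the sacrum stride displacement", {
  co <- cached_cohort(noise_free_config(n = 1, seed = 9))
  rec <- co$trials[[1]]
  ev <- detect_events(rec)
  cyc <- segment_cycles(ev, rec$paretic_side)
  st <- spatiotemporal(rec, ev)
  sac <- rec$markers$sacrum
  for (i in seq_len(nrow(cyc))) {
    stride_disp <- sac[cyc[i, 2], 1] - sac[cyc[i, 1], 1]
    dur <- (cyc[i, 2] - cyc[i, 1]) / rec$sample_rate
    expect_equal(unname(st$gait_velocity[i] * dur), unname(stride_disp), tolerance = 0.02)
  }
})

test_that("foot clearance recovers the injected toe lift and scales linearly", {
  base <- c(no_assistance = 0.18, afo = 0.18, newgait_dorsiflexion = 0.18,
            newgait_full = 0.18)
  zero <- base * 0
  cfg1 <- noise_free_config(n = 1, seed = 13, clearance_mean = base,
                            clearance_sd = zero)
  cfg2 <- noise_free_config(n = 1, seed = 13, clearance_mean = base / 2,
                            clearance_sd = zero)
  co1 <- generate_cohort(cfg1)
  co2 <- generate_cohort(cfg2)
  cl <- function(co, i) {
    rec <- co$trials[[i]]
    attr(spatiotemporal(rec, detect_events(rec)), "stride_average")[["foot_clearance"]]
  }
  for (i in c(1, 4, 7, 10)) {
    c1 <- cl(co1, i)
    c2 <- cl(co2, i)
    expect_equal(c1, 0.18, tolerance = 0.005 / 0.18)
    expect_gte(c1, 0)
    expect_equal(c1 / c2, 2, tolerance = 0.06)
  }
})

test_that("double support is 100% when both feet never leave the ground", {
  rec <- standing_recording(speed = 0.5)
  n <- nrow(rec$markers$sacrum)
  ev <- structure(list(left = list(contacts = c(1L, round(n / 2)), toeoffs = integer(0)),
                       right = list(contacts = 1L, toeoffs = integer(0)),
                       sample_rate = rec$sample_rate, flags = character(0)),
                  class = "gait_cycle_set")
  st <- spatiotemporal(rec, ev, side = "left")
  expect_equal(st$double_support, 100)
})

test_that("double support is flagged undefined without contralateral events", {
  rec <- standing_recording(speed = 0.5)
  n <- nrow(rec$markers$sacrum)
  ev <- structure(list(left = list(contacts = c(1L, round(n / 2)),
                                   toeoffs = round(n / 3)),
                       right = list(contacts = integer(0), toeoffs = integer(0)),
                       sample_rate = rec$sample_rate, flags = character(0)),
                  class = "gait_cycle_set")
  st <- spatiotemporal(rec, ev, side = "left")
  expect_true(is.na(st$double_support))
  expect_true(is.finite(st$gait_velocity))
  expect_match(attr(st, "flags"), "contralateral")
})

test_that("spatiotemporal metrics are invariant to horizontal rigid motion", {
  co <- cached_cohort(noise_free_config(n = 1, seed = 9))
  rec <- co$trials[[1]]
  st0 <- attr(spatiotemporal(rec, detect_events(rec)), "stride_average")
  th <- -60 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rec2 <- rec
  for (nm in names(rec2$markers)) {
    m <- rec2$markers[[nm]]
    m[, 1:2] <- sweep(m[, 1:2] %*% R, 2, c(-7, 3), `+`)
    rec2$markers[[nm]] <- m
  }
  st1 <- attr(spatiotemporal(rec2, detect_events(rec2)), "stride_average")
  expect_equal(st1, st0, tolerance = 1e-6)
})
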