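test_that("speed of constant and uniform motion matches closed forms", {
  n <- 50
  still <- tibble::tibble(
    t_s = seq(0, by = 1 / 240, length.out = n),
    x_cm = 1, y_cm = 2, z_cm = 3
  )
  expect_equal(compute_speed(still), rep(0, n))
  straight <- tibble::tibble(
    t_s = seq(0, 1, length.out = 241),
    x_cm = seq(0, 10, length.out = 241), y_cm = 0, z_cm = 0
  )
  v <- compute_speed(straight)
  expect_equal(v[2:240], rep(10, 239), tolerance = 1e-9)
  expect_error(compute_speed(still[1:2, ]), "3 samples")
})

test_that("minimum-jerk speed peaks at 1.875 D/T mid-movement", {
  tt <- seq(0, 0.5, by = 1 / 240)
  s <- tibble::tibble(
    t_s = tt, x_cm = 30 * min_jerk(tt / 0.5), y_cm = 0, z_cm = 0
  )
  v <- compute_speed(s)
  expect_equal(max(v), 1.875 * 30 / 0.5, tolerance = 1e-3)
  expect_equal(tt[which.max(v)], 0.25, tolerance = 1 / 240 + 1e-9)
})

test_that("landmarks of a symmetric noiseless reach match closed forms", {
  cfg <- noiseless_config() # peak_frac 0.5
  tr <- generate_trial(cfg, "younger", overrides = clean_overrides(
    latency_ms = 300, duration_ms = 500
  ))$trial
  prof <- kinematic_profile(filter_trial(tr))
  dt_ms <- 1000 / cfg$sampling_rate_hz
  expect_equal(prof$reach_latency_ms, 300, tolerance = dt_ms)
  expect_equal(prof$reach_duration_ms, 500, tolerance = dt_ms)
  expect_equal(prof$acceleration_time_ms, 250, tolerance = dt_ms + 1e-9)
  expect_equal(prof$deceleration_time_ms, 250, tolerance = dt_ms + 1e-9)
  D <- sqrt(target_position("none")[["y"]]^2 + 40^2) # start-to-target distance
  expect_equal(prof$peak_velocity_cms, 1.875 * D / 0.5, tolerance = 0.01 * 1.875 * D / 0.5)
  expect_false(prof$degenerate)
})

test_that("a late corrective submovement lengthens the deceleration phase", {
  cfg <- noiseless_config()
  tr <- generate_trial(cfg, "younger",
    condition = "200", direction = "right",
    overrides = clean_overrides(
      latency_ms = 300, duration_ms = 500,
      correction = TRUE, correction_latency_ms = 150
    )
  )$trial
  prof <- kinematic_profile(filter_trial(tr))
  expect_gt(prof$deceleration_time_ms, prof$acceleration_time_ms)
})

test_that("event arithmetic gives latency and duration directly", {
  s <- tibble::tibble(
    t_s = seq(0.30, 0.85, by = 1 / 240)
  )
  s$x_cm <- seq(0, 5, length.out = nrow(s))
  s$y_cm <- 0
  s$z_cm <- seq(40, 0, length.out = nrow(s))
  tr <- reach_trial(
    "P", "younger", 1L, 1L, "none", "none",
    target_onset_s = 0, reach_onset_s = 0.30, touch_s = 0.85,
    touch_x_cm = 5, touch_y_cm = 0, samples = s
  )
  prof <- kinematic_profile(tr)
  expect_equal(prof$reach_latency_ms, 300)
  expect_equal(prof$reach_duration_ms, 550)
  expect_equal(
    prof$acceleration_time_ms + prof$deceleration_time_ms,
    prof$reach_duration_ms
  )
})

test_that("acceleration plus deceleration equals duration on generated trials", {
  cfg <- generator_config()
  set.seed(14)
  for (i in 1:10) {
    tr <- generate_trial(cfg, "older",
      condition = "0", direction = "left",
      overrides = clean_overrides()
    )$trial
    prof <- kinematic_profile(filter_trial(tr))
    expect_equal(
      prof$acceleration_time_ms + prof$deceleration_time_ms,
      prof$reach_duration_ms,
      tolerance = 1e-9
    )
  }
})

test_that("peak velocity is invariant under time reversal", {
  cfg <- noiseless_config()
  tr <- generate_trial(cfg, "younger", overrides = clean_overrides())$trial
  s <- movement_samples(tr)
  rev_s <- tibble::tibble(
    t_s = s$t_s,
    x_cm = rev(s$x_cm), y_cm = rev(s$y_cm), z_cm = rev(s$z_cm)
  )
  expect_equal(max(compute_speed(s)), max(compute_speed(rev_s)), tolerance = 1e-9)
})

test_that("absolute x accuracy follows the arctangent and is unsigned", {
  cfg <- noiseless_config()
  tr <- generate_trial(cfg, "younger", overrides = clean_overrides())$trial
  expect_equal(absolute_x_accuracy(tr), 0, tolerance = 1e-9)
  tr_l <- tr
  tr_l$touch_x_cm <- -7.0530
  tr_r <- tr
  tr_r$touch_x_cm <- 7.0530
  expect_equal(absolute_x_accuracy(tr_l, final_target_x_cm = 0), 10, tolerance = 1e-3)
  expect_equal(
    absolute_x_accuracy(tr_l, final_target_x_cm = 0),
    absolute_x_accuracy(tr_r, final_target_x_cm = 0)
  )
  # an uncorrected perturbed trial misses by the full eccentricity
  miss <- generate_trial(cfg, "younger",
    condition = "0", direction = "right",
    overrides = clean_overrides(correction = FALSE)
  )$trial
  expect_equal(absolute_x_accuracy(miss), 10, tolerance = 1e-6)
})
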