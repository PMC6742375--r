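test_that("default sessions hold the designed trial mix", {
  cfg <- noiseless_config()
  out <- generate_session(cfg, "P01", "younger", seed = 5)
  info <- session_info(out$session)
  expect_equal(length(out$session), 480)
  expect_equal(sum(info$condition == "none"), 240)
  expect_equal(sum(info$direction == "left"), 120)
  expect_equal(sum(info$direction == "right"), 120)
  # perturbation times split evenly within each direction
  counts <- table(info$condition[info$condition != "none"], info$direction[info$condition != "none"])
  expect_true(all(counts == 60))
})

test_that("sessions are bit-reproducible under a fixed seed", {
  cfg <- generator_config() # full noise and contaminants
  a <- generate_session(cfg, "P01", "older", seed = 99)
  b <- generate_session(cfg, "P01", "older", seed = 99)
  expect_identical(a, b)
})

test_that("noiseless static trials land exactly on the initial target", {
  cfg <- noiseless_config()
  out <- generate_trial(cfg, "younger", overrides = clean_overrides())
  tr <- out$trial
  tgt <- target_position("none")
  expect_equal(tr$touch_x_cm, tgt[["x"]], tolerance = 1e-12)
  expect_equal(tr$touch_y_cm, tgt[["y"]], tolerance = 1e-12)
  expect_true(is.na(out$ground_truth$true_correction_onset_ms))
  # trajectory ends on the screen plane
  expect_equal(tr$samples$z_cm[nrow(tr$samples)], 0, tolerance = 1e-12)
})

test_that("uncorrected perturbed trials equal the unperturbed template exactly", {
  cfg <- noiseless_config()
  fixed <- clean_overrides(
    foreperiod_s = 0.7, latency_ms = 266, duration_ms = 496, correction = FALSE
  )
  template <- generate_trial(cfg, "younger", overrides = clean_overrides(
    foreperiod_s = 0.7, latency_ms = 266, duration_ms = 496
  ))$trial
  for (dir in c("left", "right")) {
    pert <- generate_trial(cfg, "younger",
      condition = "0", direction = dir,
      overrides = fixed
    )$trial
    expect_identical(pert$samples$x_cm, template$samples$x_cm)
  }
})

test_that("injected correction onsets are recoverable by template differencing", {
  cfg <- noiseless_config()
  dt_ms <- 1000 / cfg$sampling_rate_hz
  fixed <- list(foreperiod_s = 0.7, latency_ms = 266, duration_ms = 496)
  template <- generate_trial(
    cfg, "younger",
    overrides = c(clean_overrides(), fixed)
  )$trial
  for (onset in c(120, 160, 200)) {
    pert <- generate_trial(cfg, "younger",
      condition = "0", direction = "right",
      overrides = c(
        clean_overrides(correction = TRUE, correction_latency_ms = onset),
        fixed
      )
    )$trial
    t_dep <- oracle_template_departure(pert, template)
    dep_ms <- (t_dep - pert$perturbation_s) * 1000
    expect_lte(abs(dep_ms - onset), dt_ms + 1e-9)
  }
})

test_that("zero correction probability yields no injected corrections", {
  cfg <- noiseless_config(correction_prob = 0)
  out <- generate_session(cfg, "P01", "younger", seed = 3)
  expect_true(all(!out$ground_truth$correction))
  expect_true(all(is.na(out$ground_truth$true_correction_onset_ms)))
})

test_that("injection frequencies track the configured per-cell probabilities", {
  # older-group probabilities per cell; 120 trials per cell
  cfg <- noiseless_config()
  probs <- cfg$groups$older$correction_prob
  set.seed(21)
  for (cell in names(probs)) {
    parts <- strsplit(cell, "_")[[1]]
    inj <- vapply(1:120, function(i) {
      generate_trial(cfg, "older",
        condition = parts[1], direction = parts[2],
        trial = i, overrides = clean_overrides()
      )$ground_truth$correction
    }, logical(1))
    p <- probs[[cell]]
    se <- sqrt(p * (1 - p) / 120)
    expect_lte(abs(mean(inj) - p), max(3 * se, 1e-12))
  }
})

test_that("impossible correction latencies fall back to no correction", {
  gp <- group_params(
    correction_latency_mean_ms = 2000, correction_latency_sd_ms = 0,
    reach_duration_sd_ms = 0, reach_latency_sd_ms = 0,
    artifact_rate = 0, outlier_rate = 0
  )
  cfg <- generator_config(
    groups = list(younger = gp),
    endpoint_sd_cm = 0, wobble_sd_cm = 0, noise_sd_cm = 0
  )
  out <- generate_trial(cfg, "younger",
    condition = "0", direction = "right",
    overrides = clean_overrides(correction = TRUE)
  )
  expect_false(out$ground_truth$correction)
  expect_true(out$ground_truth$redraw_exhausted)
})

test_that("perturbation events respect the schedule", {
  cfg <- noiseless_config()
  for (cond in c("0", "200")) {
    tr <- generate_trial(cfg, "younger",
      condition = cond, direction = "left",
      overrides = clean_overrides()
    )$trial
    expect_equal(
      tr$perturbation_s - tr$reach_onset_s, as.numeric(cond) / 1000,
      tolerance = 1e-12
    )
  }
})
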