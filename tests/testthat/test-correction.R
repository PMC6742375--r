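make_step_probe <- function(template, condition, direction, offset_cm,
                            onset_ms_after_pert = 0) {
  # template trial turned into a perturbed trial whose x deviates by a
  # constant offset from (perturbation + onset) until touch
  s <- template$samples
  pert_s <- template$reach_onset_s + as.numeric(condition) / 1000
  from <- pert_s + onset_ms_after_pert / 1000 - 1e-9
  sgn <- if (direction == "right") 1 else -1
  s$x_cm <- s$x_cm + sgn * offset_cm * (s$t_s >= from)
  reach_trial(
    template$participant, template$group, template$block, template$trial,
    condition = condition, direction = direction,
    target_onset_s = template$target_onset_s,
    reach_onset_s = template$reach_onset_s,
    touch_s = template$touch_s,
    perturbation_s = pert_s,
    touch_x_cm = template$touch_x_cm + sgn * offset_cm,
    touch_y_cm = template$touch_y_cm,
    samples = s, sampling_rate_hz = template$sampling_rate_hz
  )
}

test_that("envelopes of identical trials collapse to the mean", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 12, filter = FALSE)
  env <- build_envelope(trials, grouping = "P1")
  expect_true(all(env$bands$sd_x_cm == 0))
  expect_true(all(env$bands$n == 12))
})

test_that("envelope mean, SD and bounds match the two-point case", {
  cfg <- noiseless_config()
  base <- make_envelope_trials(cfg, 2, filter = FALSE)
  base[[1]]$samples$x_cm <- base[[1]]$samples$x_cm + 1
  base[[2]]$samples$x_cm <- base[[2]]$samples$x_cm + 3
  env <- build_envelope(base, k = 1.5, min_support = 2, grouping = "pair")
  j <- 10
  expect_equal(env$bands$mean_x_cm[j], 2, tolerance = 1e-9)
  expect_equal(env$bands$sd_x_cm[j], sqrt(2), tolerance = 1e-9)
  lo <- env$bands$mean_x_cm[j] - env$k * env$bands$sd_x_cm[j]
  hi <- env$bands$mean_x_cm[j] + env$k * env$bands$sd_x_cm[j]
  expect_equal(c(lo, hi), c(2 - 1.5 * sqrt(2), 2 + 1.5 * sqrt(2)), tolerance = 1e-9)
})

test_that("envelope support is non-increasing for unequal trial lengths", {
  cfg <- generator_config(
    groups = list(younger = group_params(
      reach_duration_sd_ms = 80, artifact_rate = 0, outlier_rate = 0
    )),
    endpoint_sd_cm = 0, wobble_sd_cm = 0, noise_sd_cm = 0
  )
  set.seed(17)
  trials <- make_envelope_trials(cfg, 15, filter = FALSE)
  env <- build_envelope(trials, min_support = 2, grouping = "varied")
  expect_true(all(diff(env$bands$n) <= 0))
})

test_that("too few envelope trials raise an error naming the unit", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 3, filter = FALSE)
  expect_error(build_envelope(trials, grouping = "P07 block 2"), "P07 block 2")
})

test_that("a trial equal to the envelope mean is never a correction", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 20, filter = FALSE)
  env <- build_envelope(trials, grouping = "P")
  probe <- make_step_probe(trials[[1]], "0", "right", offset_cm = 0)
  res <- detect_correction(probe, env)
  expect_false(res$detected)
  expect_true(is.na(res$correction_latency_ms))
})

test_that("a deviation starting 150 ms post perturbation is timed to one sample", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 20, filter = FALSE)
  env <- build_envelope(trials, grouping = "P")
  dt_ms <- 1000 / cfg$sampling_rate_hz
  for (dir in c("left", "right")) {
    probe <- make_step_probe(trials[[1]], "0", dir,
      offset_cm = 5, onset_ms_after_pert = 150
    )
    res <- detect_correction(probe, env)
    expect_true(res$detected)
    expect_lte(abs(res$correction_latency_ms - 150), dt_ms + 1e-9)
  }
})

test_that("a trace outside the band from perturbation onset hits the 80 ms floor", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 20, filter = FALSE)
  env <- build_envelope(trials, grouping = "P")
  probe <- make_step_probe(trials[[1]], "0", "right", offset_cm = 5)
  res <- detect_correction(probe, env)
  expect_true(res$detected)
  expect_identical(res$correction_latency_ms, 80)
})

test_that("opposite-side excursions are logged but never counted", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 20, filter = FALSE)
  env <- build_envelope(trials, grouping = "P")
  # deviates leftward although the perturbation went right
  probe <- make_step_probe(trials[[1]], "0", "left", offset_cm = 5)
  probe$direction <- "right"
  res <- detect_correction(probe, env)
  expect_false(res$detected)
  expect_true(res$opposite_crossing)
})

test_that("detection requires a perturbed trial", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 20, filter = FALSE)
  env <- build_envelope(trials, grouping = "P")
  expect_error(detect_correction(trials[[1]], env), "perturbed")
})

test_that("path linearity matches hand-computed geometries", {
  # collinear path
  tau <- seq(0, 1, length.out = 50)
  col <- tibble::tibble(
    x_cm = 0, y_cm = 3.15 * tau, z_cm = 40 * (1 - tau)
  )
  pl <- path_linearity(col)
  expect_lt(pl$L, 1e-7)
  # isoceles apex: A = 5, B = 10, L = 0.5
  tri <- tibble::tibble(x_cm = c(0, 5, 10), y_cm = c(0, 5, 0), z_cm = 0)
  pl <- path_linearity(tri)
  expect_equal(pl$A_cm, 5)
  expect_equal(pl$B_cm, 10)
  expect_equal(pl$L, 0.5)
  expect_equal(pl$argmax, 2L)
})

test_that("a dense semicircular arc approaches L = 0.5", {
  th <- seq(0, pi, length.out = 1e4)
  r <- 3.7
  arc <- tibble::tibble(
    x_cm = r * cos(th), y_cm = r * sin(th), z_cm = 0
  )
  pl <- path_linearity(arc)
  expect_equal(pl$L, 0.5, tolerance = 1e-6)
})

test_that("path linearity is invariant under rigid motion and scaling", {
  set.seed(23)
  cfg <- noiseless_config()
  tr <- generate_trial(cfg, "younger",
    condition = "0", direction = "right",
    overrides = clean_overrides(correction = TRUE, correction_latency_ms = 150)
  )$trial
  s <- movement_samples(tr)
  base <- path_linearity(s)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3))) # random orthogonal matrix
    shift <- stats::rnorm(3, 0, 20)
    scale <- stats::runif(1, 0.2, 5)
    p <- as.matrix(s[c("x_cm", "y_cm", "z_cm")])
    q <- sweep(scale * (p %*% R), 2, shift, "+")
    s2 <- tibble::as_tibble(as.data.frame(q))
    names(s2) <- c("x_cm", "y_cm", "z_cm")
    pl <- path_linearity(s2)
    expect_equal(pl$L, base$L, tolerance = 1e-9)
    expect_identical(pl$argmax, base$argmax)
  }
})

test_that("degenerate paths (start = end) are flagged", {
  loop <- tibble::tibble(
    x_cm = c(0, 1, 0), y_cm = c(0, 1, 0), z_cm = c(0, 1, 0)
  )
  pl <- path_linearity(loop)
  expect_true(pl$degenerate)
  expect_true(is.na(pl$L))
})

test_that("MPO latency is plain subtraction on the shared clock", {
  cfg <- noiseless_config()
  tr <- generate_trial(cfg, "younger",
    condition = "0", direction = "right",
    overrides = clean_overrides(correction = FALSE)
  )$trial
  s <- movement_samples(tr)
  # pick the sample closest to perturbation + 200 ms
  i <- which.min(abs(s$t_s - (tr$perturbation_s + 0.2)))
  lat <- mpo_latency(tr, argmax = i)
  expect_equal(lat, (s$t_s[i] - tr$perturbation_s) * 1000)
  expect_equal(lat, 200, tolerance = 1000 / cfg$sampling_rate_hz)
})

test_that("MPO latency is undefined for non-perturbed trials", {
  cfg <- noiseless_config()
  tr <- generate_trial(cfg, "younger", overrides = clean_overrides())$trial
  expect_error(mpo_latency(tr), "non-perturbed")
})

test_that("the MPO of a corrective submovement peaks after the detected onset", {
  cfg <- noiseless_config()
  trials <- make_envelope_trials(cfg, 20, filter = FALSE)
  env <- build_envelope(trials, grouping = "P")
  tr <- generate_trial(cfg, "younger",
    condition = "0", direction = "right",
    overrides = clean_overrides(
      latency_ms = 266, duration_ms = 496,
      correction = TRUE, correction_latency_ms = 160
    )
  )$trial
  det <- detect_correction(tr, env)
  s <- movement_samples(tr)
  pl <- path_linearity(s)
  # oracle: brute-force perpendicular-distance maximum
  orc <- oracle_mpo(s)
  expect_identical(pl$argmax, orc$argmax)
  expect_equal(pl$A_cm, orc$A, tolerance = 1e-9)
  lat_mpo <- mpo_latency(tr, pl$argmax)
  expect_true(det$detected)
  expect_gt(lat_mpo, det$correction_latency_ms)
})

test_that("implementation matches brute-force oracles on mixed default trials", {
  cfg <- generator_config()
  set.seed(41)
  env <- build_envelope(make_envelope_trials(cfg, 30), grouping = "P")
  for (i in 1:50) {
    cond <- sample(c("0", "200"), 1)
    dir <- sample(c("left", "right"), 1)
    tr <- filter_trial(generate_trial(cfg, "younger",
      condition = cond, direction = dir, trial = i,
      overrides = clean_overrides()
    )$trial)
    det <- detect_correction(tr, env)
    lat_oracle <- oracle_detect_latency(tr, env)
    expect_identical(det$detected, !is.na(lat_oracle))
    if (det$detected) {
      expect_equal(det$correction_latency_ms, lat_oracle, tolerance = 1e-9)
    }
    s <- movement_samples(tr)
    pl <- path_linearity(s)
    orc <- oracle_mpo(s)
    expect_identical(pl$argmax, orc$argmax)
    expect_equal(pl$L, orc$L, tolerance = 1e-9)
  }
})

test_that("correction frequencies tabulate detections per cell", {
  res <- tibble::tibble(
    group = rep("younger", 6),
    condition = rep(c("0", "200"), each = 3),
    direction = rep("left", 6),
    detected = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  tab <- correction_frequency(res)
  expect_equal(tab$pct_corrected[tab$condition == "0"], 100)
  expect_equal(tab$pct_corrected[tab$condition == "200"], 100 / 3, tolerance = 1e-9)
})
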