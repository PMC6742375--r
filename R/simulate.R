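#' Generate one synthetic reach trial
#'
#' Simulates a single double-step pointing trial as recorded by a 240 Hz
#' position tracker. The primary movement travels from the start position
#' `(0, 0, viewing_distance)` to the initial target on the screen plane along
#' a smooth profile with a configurable peak-velocity time
#' ([reach_profile()]); the horizontal position of an unperturbed reach is
#' flat at zero apart from motor scatter and sensor noise. On perturbed trials
#' where a correction is injected, an additive minimum-jerk corrective
#' submovement toward the displaced target begins at perturbation time plus
#' the drawn correction latency and completes at touch (superposition, the
#' standard submovement-decomposition convention). Per-trial motor scatter
#' has an endpoint-bias component scaling with movement progress and a
#' transient mid-flight component peaking at mid-movement; sensor noise is
#' white Gaussian, low-pass filtered at `noise_corner_hz`.
#'
#' Sample times are anchored to the reach-onset grid (reach onset falls
#' exactly on a sample), which mirrors tracker recordings aligned offline and
#' makes cross-trial averaging exact. Timing draws are redrawn when
#' impossible (non-positive durations, correction onset too close to touch);
#' if the redraw budget is exhausted the trial falls back to no injected
#' correction and this is flagged in the ground truth.
#'
#' @param config A [generator_config()].
#' @param group Group label; must name an entry of `config$groups`.
#' @param condition `"none"`, `"0"` or `"200"` (perturbation time, ms after
#'   reach onset).
#' @param direction `"none"`, `"left"` or `"right"`.
#' @param participant,block,trial Identifiers recorded on the trial.
#' @param participant_offsets Named numeric vector `c(latency_ms=, duration_ms=)`
#'   of stable per-participant shifts added to the group timing means.
#' @param overrides Named list pinning individual draws, used for validation:
#'   any of `foreperiod_s`, `latency_ms`, `duration_ms`, `correction` (logical),
#'   `correction_latency_ms`, `endpoint_bias_cm` (length-2 x/y), `artifact`
#'   (`NA`, `"missing_touch"`, `"premature_start"`, `"sample_gap"`,
#'   `"empty_trajectory"`), `outlier` (logical).
#' @return A list with elements `trial` (a [reach_trial()]) and
#'   `ground_truth` (one-row tibble: injected correction onset in ms from
#'   perturbation or `NA`, artifact type, outlier flag).
#' @export
generate_trial <- function(config, group,
                           condition = "none", direction = "none",
                           participant = "P01", block = 1L, trial = 1L,
                           participant_offsets = c(latency_ms = 0, duration_ms = 0),
                           overrides = list()) {
  stopifnot(inherits(config, "ds_generator_config"))
  gp <- config$groups[[group]]
  if (is.null(gp)) {
    stop(sprintf("Group '%s' is not configured.", group), call. = FALSE)
  }
  condition <- match.arg(as.character(condition), c("none", "0", "200"))
  direction <- match.arg(direction, c("none", "left", "right"))
  fs <- config$sampling_rate_hz
  dt <- 1 / fs
  ov <- function(name, default) {
    if (!is.null(overrides[[name]])) overrides[[name]] else default
  }

  foreperiod_s <- ov(
    "foreperiod_s",
    stats::runif(1, config$foreperiod_range_ms[1], config$foreperiod_range_ms[2]) / 1000
  )
  outlier <- isTRUE(ov("outlier", stats::runif(1) < gp$outlier_rate))

  draw_positive <- function(mean, sd, floor) {
    for (i in seq_len(config$redraw_budget)) {
      v <- stats::rnorm(1, mean, sd)
      if (v >= floor) return(v)
    }
    floor
  }
  latency_ms <- ov(
    "latency_ms",
    draw_positive(
      gp$reach_latency_mean_ms + participant_offsets[["latency_ms"]],
      gp$reach_latency_sd_ms, 100
    )
  )
  duration_ms <- ov(
    "duration_ms",
    draw_positive(
      gp$reach_duration_mean_ms + participant_offsets[["duration_ms"]],
      gp$reach_duration_sd_ms, 150
    )
  )
  if (outlier) {
    latency_ms <- latency_ms * config$outlier_latency_factor
    duration_ms <- duration_ms * config$outlier_duration_factor
  }

  perturbed <- condition != "none"
  correction <- FALSE
  if (perturbed) {
    p <- gp$correction_prob[[paste0(condition, "_", direction)]]
    correction <- isTRUE(ov("correction", stats::runif(1) < p))
  }
  base_duration_ms <- duration_ms
  peak_frac <- gp$peak_frac
  if (correction) {
    # corrections prolong the movement; the extra time is spent decelerating
    # (homing), so the time of peak velocity is left where the base reach put it
    duration_ms <- duration_ms + config$duration_extension_ms[[condition]]
    peak_frac <- peak_frac * base_duration_ms / duration_ms
  }

  n_pre <- max(1L, round(latency_ms / 1000 * fs))
  latency_s <- n_pre * dt
  n_post <- max(2L, round(duration_ms / 1000 * fs))
  duration_s <- n_post * dt
  target_onset_s <- foreperiod_s
  reach_onset_s <- target_onset_s + latency_s
  touch_s <- reach_onset_s + duration_s
  perturbation_s <- if (perturbed) reach_onset_s + as.numeric(condition) / 1000 else NA_real_

  corr_latency_ms <- NA_real_
  redraw_exhausted <- FALSE
  if (correction) {
    pert_rel_ms <- as.numeric(condition)
    forced <- ov("correction_latency_ms", NULL)
    cl_mean <- gp$correction_latency_mean_ms +
      config$correction_latency_condition_offset_ms[[condition]]
    ok <- function(l) {
      l >= 90 && pert_rel_ms + l + config$min_submovement_ms <= duration_s * 1000
    }
    if (!is.null(forced)) {
      corr_latency_ms <- forced
      if (!ok(forced)) {
        stop("Forced correction latency leaves no room for a submovement.", call. = FALSE)
      }
    } else {
      found <- FALSE
      for (i in seq_len(config$redraw_budget)) {
        l <- stats::rnorm(1, cl_mean, gp$correction_latency_sd_ms)
        if (ok(l)) {
          corr_latency_ms <- l
          found <- TRUE
          break
        }
      }
      if (!found) {
        correction <- FALSE
        redraw_exhausted <- TRUE
      }
    }
  }

  bias <- ov("endpoint_bias_cm", stats::rnorm(2, 0, config$endpoint_sd_cm))
  wobble <- ov("wobble_cm", stats::rnorm(2, 0, config$wobble_sd_cm))

  vd <- config$viewing_distance_cm
  tgt0 <- target_position(
    "none", config$perturbation_ecc_deg,
    config$target_elevation_deg, vd
  )
  t_s <- reach_onset_s + (-n_pre:n_post) * dt
  tau <- pmax(0, t_s - reach_onset_s) / duration_s
  m <- reach_profile(tau, peak_frac)
  bump <- 4 * m * (1 - m) # transient mid-flight deviation, zero at rest and touch
  x <- (tgt0[["x"]] + bias[1]) * m + wobble[1] * bump
  y <- (tgt0[["y"]] + bias[2]) * m + wobble[2] * bump
  z <- vd * (1 - m)

  sub_amp <- 0
  if (correction) {
    tgt_p <- target_position(
      direction, config$perturbation_ecc_deg,
      config$target_elevation_deg, vd
    )
    sub_amp <- config$correction_gain * (tgt_p[["x"]] - tgt0[["x"]])
    tc_s <- perturbation_s + corr_latency_ms / 1000
    sub_dur_s <- min(config$submovement_duration_ms / 1000, touch_s - tc_s)
    tau_c <- (t_s - tc_s) / sub_dur_s
    x <- x + sub_amp * min_jerk(tau_c)
  }

  touch_x <- x[length(x)]
  touch_y <- y[length(y)]

  if (config$noise_sd_cm > 0) {
    n <- length(t_s)
    noise <- matrix(stats::rnorm(3 * n, 0, config$noise_sd_cm), ncol = 3)
    if (n >= 24 && config$noise_corner_hz < fs / 2) {
      noise <- apply(noise, 2, lowpass_filter,
        sampling_rate_hz = fs,
        cutoff_hz = config$noise_corner_hz, order = 2
      )
    }
    x <- x + noise[, 1]
    y <- y + noise[, 2]
    z <- z + noise[, 3]
  }

  samples <- tibble::tibble(t_s = t_s, x_cm = x, y_cm = y, z_cm = z)

  artifact <- ov("artifact", {
    if (stats::runif(1) < gp$artifact_rate) {
      sample(c("missing_touch", "premature_start", "sample_gap", "empty_trajectory"), 1)
    } else {
      NA_character_
    }
  })
  if (!is.na(artifact)) {
    if (artifact == "missing_touch") {
      touch_s <- NA_real_
      touch_x <- NA_real_
      touch_y <- NA_real_
    } else if (artifact == "premature_start") {
      reach_onset_s <- target_onset_s - 0.05
    } else if (artifact == "sample_gap") {
      from <- n_pre + max(2L, n_post %/% 3)
      drop <- from:(from + 4L)
      drop <- drop[drop <= nrow(samples) - 2L]
      if (length(drop)) samples <- samples[-drop, , drop = FALSE]
    } else if (artifact == "empty_trajectory") {
      samples <- samples[1:2, , drop = FALSE]
    }
  }

  tr <- reach_trial(
    participant = participant, group = group, block = block, trial = trial,
    condition = condition, direction = direction,
    target_onset_s = target_onset_s, reach_onset_s = reach_onset_s,
    touch_s = touch_s, perturbation_s = perturbation_s,
    touch_x_cm = touch_x, touch_y_cm = touch_y,
    samples = samples, sampling_rate_hz = fs
  )
  gt <- tibble::tibble(
    participant = as.character(participant),
    group = as.character(group),
    block = as.integer(block),
    trial = as.integer(trial),
    condition = condition,
    direction = direction,
    correction = correction,
    true_correction_onset_ms = if (correction) corr_latency_ms else NA_real_,
    artifact = artifact,
    outlier = outlier,
    redraw_exhausted = redraw_exhausted
  )
  list(trial = tr, ground_truth = gt)
}

block_schedule <- function(config) {
  tpb <- config$trials_per_block
  times <- as.character(config$perturbation_times_ms)
  n_dir <- c(
    left = round(tpb * config$trial_mix[["left"]]),
    right = round(tpb * config$trial_mix[["right"]])
  )
  n_static <- tpb - sum(n_dir)
  if (n_static < 0) {
    stop("trial_mix does not tile trials_per_block.", call. = FALSE)
  }
  sched <- tibble::tibble(
    condition = "none", direction = "none",
    .rows = n_static
  )
  for (dir in c("left", "right")) {
    per_time <- n_dir[[dir]] %/% length(times)
    extra <- n_dir[[dir]] - per_time * length(times)
    counts <- rep(per_time, length(times)) + c(rep(1, extra), rep(0, length(times) - extra))
    for (i in seq_along(times)) {
      sched <- dplyr::bind_rows(
        sched,
        tibble::tibble(condition = times[i], direction = dir, .rows = counts[i])
      )
    }
  }
  sched
}

#' Generate a synthetic session for one participant
#'
#' Builds `blocks x trials_per_block` trials. Each block holds the exact trial
#' mix of the design (with the default mix, 40 static, 10 per perturbation
#' time x direction cell) in a randomly interleaved order. Per-participant
#' random timing offsets are drawn once and applied to every trial. Output is
#' bit-reproducible for a fixed `seed`.
#'
#' @inheritParams generate_trial
#' @param participant Participant identifier.
#' @param seed Integer seed; defaults to `config$seed`. `NULL` leaves the RNG
#'   state untouched.
#' @return A list with `session` (a [reach_session()]) and `ground_truth`
#'   (tibble, one row per trial).
#' @export
generate_session <- function(config, participant = "P01",
                             group = names(config$groups)[1],
                             seed = config$seed) {
  stopifnot(inherits(config, "ds_generator_config"))
  if (!is.null(seed)) set.seed(seed)
  gp <- config$groups[[group]]
  if (is.null(gp)) stop(sprintf("Group '%s' is not configured.", group), call. = FALSE)
  offsets <- c(
    latency_ms = stats::rnorm(1, 0, gp$participant_latency_sd_ms),
    duration_ms = stats::rnorm(1, 0, gp$participant_duration_sd_ms)
  )
  trials <- list()
  gts <- list()
  idx <- 0L
  for (b in seq_len(config$blocks)) {
    sched <- block_schedule(config)
    sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
    for (i in seq_len(nrow(sched))) {
      idx <- idx + 1L
      out <- generate_trial(
        config, group,
        condition = sched$condition[i], direction = sched$direction[i],
        participant = participant, block = b, trial = idx,
        participant_offsets = offsets
      )
      trials[[idx]] <- out$trial
      gts[[idx]] <- out$ground_truth
    }
  }
  list(
    session = reach_session(trials, config$sampling_rate_hz),
    ground_truth = dplyr::bind_rows(gts)
  )
}

#' Generate a multi-participant synthetic cohort
#'
#' Repeats [generate_session()] for several participants per group and pools
#' the result into one session. Participant identifiers are
#' `<group>_<number>`.
#'
#' @inheritParams generate_session
#' @param n_per_group Named integer vector: participants per group label.
#' @return A list with `session` and `ground_truth`, as [generate_session()].
#' @export
generate_cohort <- function(config,
                            n_per_group = c(younger = 2, older = 2),
                            seed = config$seed) {
  stopifnot(inherits(config, "ds_generator_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% names(config$groups))) {
    stop("`n_per_group` must be named by configured groups.", call. = FALSE)
  }
  trials <- list()
  gts <- list()
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      out <- generate_session(
        config,
        participant = sprintf("%s_%02d", g, i),
        group = g, seed = NULL
      )
      trials <- c(trials, out$session$trials)
      gts[[length(gts) + 1L]] <- out$ground_truth
    }
  }
  list(
    session = reach_session(trials, config$sampling_rate_hz),
    ground_truth = dplyr::bind_rows(gts)
  )
}
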