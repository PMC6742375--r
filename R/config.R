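#' Per-group timing and correction parameters for the session generator
#'
#' Bundles the group-dependent parameters of the synthetic reach generator.
#' The shipped defaults for the two age groups (see [generator_config()])
#' encode the descriptive timing structure of a double-step pointing study:
#' older adults are slower to start (+28 ms reach latency), slower overall
#' (+36 ms reach duration), spend a larger share of the movement decelerating,
#' correct less often, and produce more contaminated trials.
#'
#' @param reach_latency_mean_ms,reach_latency_sd_ms Mean and SD of the reach
#'   latency draw (target onset to button release), ms.
#' @param reach_duration_mean_ms,reach_duration_sd_ms Mean and SD of the base
#'   reach duration draw (button release to touch), ms. The task imposes a
#'   550 ms time-pressure ceiling, so means sit below it.
#' @param peak_frac Fraction of the movement at which speed peaks (see
#'   [reach_profile()]); values below 0.5 lengthen the deceleration phase.
#' @param correction_latency_mean_ms,correction_latency_sd_ms Mean and SD of
#'   the injected corrective-submovement onset, ms after the perturbation.
#' @param correction_prob Named numeric vector of correction probabilities per
#'   perturbation condition x direction, names
#'   `c("0_left", "0_right", "200_left", "200_right")`, each in \[0, 1\].
#' @param participant_latency_sd_ms,participant_duration_sd_ms SD of
#'   per-participant random offsets (stable within a participant) added to the
#'   latency and duration means, ms.
#' @param artifact_rate Probability that a trial is contaminated by an
#'   apparatus/participant error (missing touch, premature start, dropped
#'   samples, empty trajectory).
#' @param outlier_rate Probability that a trial is a behavioural outlier
#'   (greatly inflated latency and duration).
#' @return A named list of class `ds_group_params`.
#' @export
group_params <- function(reach_latency_mean_ms = 280,
                         reach_latency_sd_ms = 35,
                         reach_duration_mean_ms = 510,
                         reach_duration_sd_ms = 50,
                         peak_frac = 0.52,
                         correction_latency_mean_ms = 300,
                         correction_latency_sd_ms = 40,
                         correction_prob = c(
                           "0_left" = 0.95, "0_right" = 0.95,
                           "200_left" = 0.65, "200_right" = 0.60
                         ),
                         participant_latency_sd_ms = 20,
                         participant_duration_sd_ms = 25,
                         artifact_rate = 0.05,
                         outlier_rate = 0.05) {
  p <- list(
    reach_latency_mean_ms = reach_latency_mean_ms,
    reach_latency_sd_ms = reach_latency_sd_ms,
    reach_duration_mean_ms = reach_duration_mean_ms,
    reach_duration_sd_ms = reach_duration_sd_ms,
    peak_frac = peak_frac,
    correction_latency_mean_ms = correction_latency_mean_ms,
    correction_latency_sd_ms = correction_latency_sd_ms,
    correction_prob = correction_prob,
    participant_latency_sd_ms = participant_latency_sd_ms,
    participant_duration_sd_ms = participant_duration_sd_ms,
    artifact_rate = artifact_rate,
    outlier_rate = outlier_rate
  )
  sds <- c(
    reach_latency_sd_ms, reach_duration_sd_ms, correction_latency_sd_ms,
    participant_latency_sd_ms, participant_duration_sd_ms
  )
  if (any(sds < 0)) stop("All SDs must be >= 0.", call. = FALSE)
  probs <- c(correction_prob, artifact_rate, outlier_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("Probabilities must lie in [0, 1].", call. = FALSE)
  }
  required <- c("0_left", "0_right", "200_left", "200_right")
  if (!all(required %in% names(correction_prob))) {
    stop(
      "`correction_prob` must name the cells ",
      paste(required, collapse = ", "), ".",
      call. = FALSE
    )
  }
  if (peak_frac <= 0 || peak_frac >= 1) {
    stop("`peak_frac` must be in (0, 1).", call. = FALSE)
  }
  structure(p, class = "ds_group_params")
}

#' Configuration of the synthetic double-step session generator
#'
#' Collects every tunable of the simulator: apparatus geometry and sampling,
#' the trial mix and perturbation schedule, per-group timing distributions,
#' corrective-submovement parameters, measurement noise, and contaminant
#' rates. Defaults emulate the recording conditions of a touchscreen
#' double-step pointing task: a 240 Hz electromagnetic tracker, 40 cm viewing
#' and reaching distance, the initial target 4.5 deg above fixation, lateral
#' perturbations of 10 deg scheduled 0 or 200 ms after reach onset on half the
#' trials (25% left, 25% right), 80 trials per block and 6 blocks (480 trials
#' per participant), and a uniform 500-1000 ms foreperiod.
#'
#' Trial-to-trial variability has three components: endpoint motor scatter
#' that grows with movement progress (SD `endpoint_sd_cm`), a transient
#' mid-flight path deviation that peaks mid-movement and vanishes at the
#' endpoints (SD `wobble_sd_cm`, modelling signal-dependent motor noise with
#' feedback homing), and sensor noise (white Gaussian positional noise of SD
#' `noise_sd_cm` low-pass filtered at `noise_corner_hz`). The motor
#' components dominate the cross-trial envelope at every phase of the reach,
#' keeping the 1.5 SD detector non-degenerate.
#'
#' @param sampling_rate_hz Tracker sampling rate, Hz (default 240).
#' @param viewing_distance_cm Eye/hand start to screen distance, cm.
#' @param target_elevation_deg Initial target elevation above fixation, deg.
#' @param perturbation_ecc_deg Lateral perturbation eccentricity, deg.
#' @param perturbation_times_ms Perturbation onsets relative to reach onset,
#'   ms (default `c(0, 200)`), split evenly within each perturbed direction.
#' @param trial_mix Named proportions of static/left/right trials, summing
#'   to 1 (default 0.5/0.25/0.25).
#' @param trials_per_block,blocks Trials per block (default 80) and number of
#'   blocks (default 6).
#' @param foreperiod_range_ms Range of the uniform variable foreperiod between
#'   fixation and target onset, ms (default 500-1000).
#' @param groups Named list of [group_params()], one per group label.
#' @param endpoint_sd_cm SD of the per-trial lateral/vertical endpoint motor
#'   scatter, cm; the deviation scales with movement progress.
#' @param wobble_sd_cm SD of the per-trial mid-flight path deviation, cm;
#'   shaped as `4 m (1 - m)` in movement progress `m`, so it peaks
#'   mid-movement and vanishes at rest and at touch (feedback homing).
#' @param noise_sd_cm SD of white Gaussian sensor noise per axis, cm,
#'   before low-pass filtering.
#' @param noise_corner_hz Corner frequency of the 2nd-order zero-phase
#'   Butterworth filter applied to the sensor noise, Hz.
#' @param correction_gain Fraction of the full target displacement covered by
#'   the injected corrective submovement (1 = lands exactly on the displaced
#'   target; below 1 models the undershoot seen in late corrections).
#' @param submovement_duration_ms Duration of the corrective submovement, ms
#'   (a fast error correction); truncated to the time remaining until touch.
#' @param duration_extension_ms Named vector: extra movement time on corrected
#'   perturbed trials, per perturbation condition (`"0"`, `"200"`), ms.
#' @param correction_latency_condition_offset_ms Named vector of additive
#'   offsets to the drawn correction latency per condition; late perturbations
#'   elicit slightly faster corrections.
#' @param outlier_latency_factor,outlier_duration_factor Multipliers applied
#'   to latency and duration on behavioural-outlier trials.
#' @param min_submovement_ms Minimum time that must remain between corrective
#'   submovement onset and touch; latencies violating it are redrawn.
#' @param redraw_budget Maximum redraws of an invalid timing draw before the
#'   trial falls back to no injected correction.
#' @param seed Optional integer seed; [generate_session()] and
#'   [generate_cohort()] are bit-reproducible given the same seed.
#' @return A named list of class `ds_generator_config`.
#' @seealso [generate_trial()], [generate_session()], [generate_cohort()]
#' @export
generator_config <- function(sampling_rate_hz = 240,
                             viewing_distance_cm = 40,
                             target_elevation_deg = 4.5,
                             perturbation_ecc_deg = 10,
                             perturbation_times_ms = c(0, 200),
                             trial_mix = c(static = 0.5, left = 0.25, right = 0.25),
                             trials_per_block = 80,
                             blocks = 6,
                             foreperiod_range_ms = c(500, 1000),
                             groups = list(
                               younger = group_params(
                                 reach_latency_mean_ms = 266,
                                 reach_duration_mean_ms = 496,
                                 peak_frac = 0.54,
                                 correction_prob = c(
                                   "0_left" = 1.00, "0_right" = 1.00,
                                   "200_left" = 0.72, "200_right" = 0.66
                                 ),
                                 artifact_rate = 0.06,
                                 outlier_rate = 0.04
                               ),
                               older = group_params(
                                 reach_latency_mean_ms = 294,
                                 reach_duration_mean_ms = 532,
                                 peak_frac = 0.50,
                                 correction_prob = c(
                                   "0_left" = 0.91, "0_right" = 0.92,
                                   "200_left" = 0.59, "200_right" = 0.48
                                 ),
                                 artifact_rate = 0.09,
                                 outlier_rate = 0.10
                               )
                             ),
                             endpoint_sd_cm = 0.35,
                             wobble_sd_cm = 0.25,
                             noise_sd_cm = 0.05,
                             noise_corner_hz = 10,
                             correction_gain = 0.8,
                             submovement_duration_ms = 200,
                             duration_extension_ms = c("0" = 18, "200" = 92),
                             correction_latency_condition_offset_ms = c("0" = 0, "200" = -32.68),
                             outlier_latency_factor = 2.5,
                             outlier_duration_factor = 1.8,
                             min_submovement_ms = 60,
                             redraw_budget = 100,
                             seed = NULL) {
  if (sampling_rate_hz <= 0) stop("`sampling_rate_hz` must be > 0.", call. = FALSE)
  if (abs(sum(trial_mix) - 1) > 1e-8) {
    stop("`trial_mix` must sum to 1.", call. = FALSE)
  }
  if (!all(c("static", "left", "right") %in% names(trial_mix))) {
    stop("`trial_mix` must name static, left and right.", call. = FALSE)
  }
  if (any(trial_mix < 0)) stop("`trial_mix` proportions must be >= 0.", call. = FALSE)
  if (endpoint_sd_cm < 0 || wobble_sd_cm < 0 || noise_sd_cm < 0) {
    stop("Noise SDs must be >= 0.", call. = FALSE)
  }
  if (length(foreperiod_range_ms) != 2 || diff(foreperiod_range_ms) < 0) {
    stop("`foreperiod_range_ms` must be an increasing pair.", call. = FALSE)
  }
  if (correction_gain <= 0 || correction_gain > 1) {
    stop("`correction_gain` must be in (0, 1].", call. = FALSE)
  }
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  for (g in groups) {
    if (!inherits(g, "ds_group_params")) {
      stop("Each element of `groups` must come from group_params().", call. = FALSE)
    }
  }
  structure(
    list(
      sampling_rate_hz = sampling_rate_hz,
      viewing_distance_cm = viewing_distance_cm,
      target_elevation_deg = target_elevation_deg,
      perturbation_ecc_deg = perturbation_ecc_deg,
      perturbation_times_ms = perturbation_times_ms,
      trial_mix = trial_mix,
      trials_per_block = trials_per_block,
      blocks = blocks,
      foreperiod_range_ms = foreperiod_range_ms,
      groups = groups,
      endpoint_sd_cm = endpoint_sd_cm,
      wobble_sd_cm = wobble_sd_cm,
      noise_sd_cm = noise_sd_cm,
      noise_corner_hz = noise_corner_hz,
      correction_gain = correction_gain,
      submovement_duration_ms = submovement_duration_ms,
      duration_extension_ms = duration_extension_ms,
      correction_latency_condition_offset_ms = correction_latency_condition_offset_ms,
      outlier_latency_factor = outlier_latency_factor,
      outlier_duration_factor = outlier_duration_factor,
      min_submovement_ms = min_submovement_ms,
      redraw_budget = redraw_budget,
      seed = seed
    ),
    class = "ds_generator_config"
  )
}

#' @export
print.ds_generator_config <- function(x, ...) {
  cat("<double-step generator config>\n")
  cat(sprintf(
    "  %g Hz tracker, %g cm viewing distance, target +%g deg, perturbation +/-%g deg\n",
    x$sampling_rate_hz, x$viewing_distance_cm, x$target_elevation_deg,
    x$perturbation_ecc_deg
  ))
  cat(sprintf(
    "  %d blocks x %d trials, mix static/left/right = %s, perturbation at %s ms\n",
    x$blocks, x$trials_per_block,
    paste(x$trial_mix, collapse = "/"),
    paste(x$perturbation_times_ms, collapse = "/")
  ))
  cat(sprintf(
    "  groups: %s; endpoint SD %g cm, sensor noise SD %g cm (%g Hz)\n",
    paste(names(x$groups), collapse = ", "),
    x$endpoint_sd_cm, x$noise_sd_cm, x$noise_corner_hz
  ))
  invisible(x)
}

#' Build a generator configuration from a YAML/JSON key-value file
#'
#' Reads a flat key-value file whose names match [generator_config()] and
#' [group_params()] arguments. Group entries nest under `groups:`.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A `ds_generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$groups)) {
    raw$groups <- lapply(raw$groups, function(g) {
      if (!is.null(g$correction_prob)) g$correction_prob <- unlist(g$correction_prob)
      do.call(group_params, g)
    })
  }
  for (nm in c(
    "perturbation_times_ms", "trial_mix", "foreperiod_range_ms",
    "duration_extension_ms", "correction_latency_condition_offset_ms"
  )) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}
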