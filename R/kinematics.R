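#' Tangential speed of a position series
#'
#' Central-difference differentiation of the (filtered) position stream:
#' interior samples use `(p[i+1] - p[i-1]) / (t[i+1] - t[i-1])` per
#' coordinate, the endpoints one-sided differences; speed is the Euclidean
#' norm over the requested coordinates in cm/s. Speed is 3D by default; a
#' horizontal-plane variant (`dims = c("x_cm", "y_cm")`) is available since
#' either convention appears in the pointing literature.
#'
#' @param samples Tibble with columns `t_s` and the coordinate columns.
#' @param dims Coordinate columns entering the norm.
#' @return Numeric vector of speeds, one per sample.
#' @export
compute_speed <- function(samples, dims = c("x_cm", "y_cm", "z_cm")) {
  stopifnot(all(c("t_s", dims) %in% names(samples)))
  n <- nrow(samples)
  if (n < 3) stop("Need at least 3 samples to differentiate.", call. = FALSE)
  t <- samples$t_s
  sq <- rep(0, n)
  for (d in dims) {
    p <- samples[[d]]
    v <- numeric(n)
    v[1] <- (p[2] - p[1]) / (t[2] - t[1])
    v[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
    i <- 2:(n - 1)
    v[i] <- (p[i + 1] - p[i - 1]) / (t[i + 1] - t[i - 1])
    sq <- sq + v^2
  }
  sqrt(sq)
}

#' Temporal kinematic landmarks of a trial
#'
#' Computes the classic dependent variables of a pointing trial from its
#' events and (filtered) samples:
#' reach latency (target onset to button release), reach duration (release to
#' touch), peak velocity and its time, acceleration time (release to peak
#' velocity) and deceleration time (peak velocity to touch). Acceleration and
#' deceleration time sum to the reach duration exactly by construction. Peak
#' velocity is searched within the movement window with ties broken by the
#' earliest sample; a peak at the first or last movement sample marks the
#' profile as degenerate (monotone speed), which is reported, not dropped.
#'
#' @param trial A [reach_trial()], already screened and filtered.
#' @param dims Coordinates entering the speed norm (see [compute_speed()]).
#' @return An object of class `ds_kinematic_profile`: a list with the speed
#'   series and scalar landmarks (`reach_latency_ms`, `reach_duration_ms`,
#'   `peak_velocity_cms`, `time_to_peak_ms`, `acceleration_time_ms`,
#'   `deceleration_time_ms`, `degenerate`).
#' @export
kinematic_profile <- function(trial, dims = c("x_cm", "y_cm", "z_cm")) {
  stopifnot(inherits(trial, "ds_trial"))
  if (is.na(trial$touch_s)) {
    stop("Trial has no touch response; it should have been screened.", call. = FALSE)
  }
  speed <- compute_speed(trial$samples, dims)
  t <- trial$samples$t_s
  eps <- 0.5 / trial$sampling_rate_hz
  win <- which(t >= trial$reach_onset_s - eps & t <= trial$touch_s + eps)
  if (length(win) < 3) stop("Movement window has fewer than 3 samples.", call. = FALSE)
  i_peak <- win[which.max(speed[win])]
  degenerate <- i_peak == win[1] || i_peak == win[length(win)]
  latency_ms <- (trial$reach_onset_s - trial$target_onset_s) * 1000
  duration_ms <- (trial$touch_s - trial$reach_onset_s) * 1000
  accel_ms <- (t[i_peak] - trial$reach_onset_s) * 1000
  structure(
    list(
      speed_cms = speed,
      t_s = t,
      reach_latency_ms = latency_ms,
      reach_duration_ms = duration_ms,
      peak_velocity_cms = speed[i_peak],
      time_to_peak_ms = accel_ms,
      acceleration_time_ms = accel_ms,
      deceleration_time_ms = duration_ms - accel_ms,
      degenerate = degenerate
    ),
    class = "ds_kinematic_profile"
  )
}

#' @export
print.ds_kinematic_profile <- function(x, ...) {
  cat(sprintf(
    "<kinematic profile> latency %.0f ms, duration %.0f ms, vpeak %.1f cm/s @ %.0f ms (acc %.0f / dec %.0f ms)%s\n",
    x$reach_latency_ms, x$reach_duration_ms, x$peak_velocity_cms,
    x$time_to_peak_ms, x$acceleration_time_ms, x$deceleration_time_ms,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Absolute horizontal endpoint accuracy in degrees of visual angle
#'
#' Unsigned horizontal distance between the touch location and the final
#' target position, expressed as a visual angle at the viewing distance: on
#' perturbed trials the final target is the displaced one. The absolute value
#' is used so that leftward and rightward misses do not cancel in averages.
#'
#' @param trial A [reach_trial()] with a recorded touch.
#' @param final_target_x_cm Horizontal position of the final target, cm. When
#'   `NULL`, derived from the trial's condition labels and the task geometry
#'   arguments.
#' @param eccentricity_deg,elevation_deg,viewing_distance_cm Task geometry
#'   used when deriving the target (defaults 10, 4.5, 40).
#' @return Accuracy in degrees (non-negative scalar).
#' @export
absolute_x_accuracy <- function(trial, final_target_x_cm = NULL,
                                eccentricity_deg = 10, elevation_deg = 4.5,
                                viewing_distance_cm = 40) {
  stopifnot(inherits(trial, "ds_trial"))
  if (is.na(trial$touch_x_cm)) {
    stop("Trial has no touch location; it should have been screened.", call. = FALSE)
  }
  if (is.null(final_target_x_cm)) {
    final_target_x_cm <- target_position(
      trial$direction, eccentricity_deg, elevation_deg, viewing_distance_cm
    )[["x"]]
  }
  abs(cm_to_dva(trial$touch_x_cm - final_target_x_cm, viewing_distance_cm))
}

#' Per-trial dependent-variable table for a session
#'
#' Runs [kinematic_profile()] and [absolute_x_accuracy()] on every trial and
#' returns one row per trial with all temporal and spatial dependent
#' variables, ready for outlier screening and summaries.
#'
#' @param session A [reach_session()], screened and filtered.
#' @param dims Coordinates entering the speed norm.
#' @inheritParams absolute_x_accuracy
#' @return A tibble, one row per trial.
#' @export
kinematics_table <- function(session, dims = c("x_cm", "y_cm", "z_cm"),
                             eccentricity_deg = 10, elevation_deg = 4.5,
                             viewing_distance_cm = 40) {
  stopifnot(inherits(session, "ds_session"))
  purrr::map_dfr(session$trials, function(tr) {
    prof <- kinematic_profile(tr, dims)
    tibble::tibble(
      participant = tr$participant,
      group = tr$group,
      block = tr$block,
      trial = tr$trial,
      condition = tr$condition,
      direction = tr$direction,
      reach_latency_ms = prof$reach_latency_ms,
      reach_duration_ms = prof$reach_duration_ms,
      peak_velocity_cms = prof$peak_velocity_cms,
      acceleration_time_ms = prof$acceleration_time_ms,
      deceleration_time_ms = prof$deceleration_time_ms,
      abs_x_accuracy_deg = absolute_x_accuracy(
        tr,
        eccentricity_deg = eccentricity_deg,
        elevation_deg = elevation_deg,
        viewing_distance_cm = viewing_distance_cm
      ),
      degenerate_profile = prof$degenerate
    )
  })
}
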