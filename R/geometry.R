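#' Convert a screen offset in centimetres to degrees of visual angle
#'
#' Screen distances are expressed as visual angles via the exact arctangent
#' relation at the given viewing distance: `deg = atan(offset / distance)`.
#' The sign of the offset is preserved, so leftward offsets map to negative
#' angles.
#'
#' @param offset_cm Numeric vector of on-screen offsets in cm.
#' @param viewing_distance_cm Distance from the eye to the screen plane in cm
#'   (must be positive). Default 40, the seated reaching distance of the task.
#' @return Numeric vector of angles in degrees.
#' @examples
#' cm_to_dva(0)            # 0
#' cm_to_dva(40, 40)       # 45
#' cm_to_dva(dva_to_cm(10))  # 10
#' @export
cm_to_dva <- function(offset_cm, viewing_distance_cm = 40) {
  if (!is.numeric(viewing_distance_cm) || any(viewing_distance_cm <= 0)) {
    stop("`viewing_distance_cm` must be positive.", call. = FALSE)
  }
  atan(offset_cm / viewing_distance_cm) * 180 / pi
}

#' Convert degrees of visual angle to a screen offset in centimetres
#'
#' Inverse of [cm_to_dva()]: `cm = distance * tan(angle)`.
#'
#' @param angle_deg Numeric vector of visual angles in degrees.
#' @inheritParams cm_to_dva
#' @return Numeric vector of on-screen offsets in cm.
#' @export
dva_to_cm <- function(angle_deg, viewing_distance_cm = 40) {
  if (!is.numeric(viewing_distance_cm) || any(viewing_distance_cm <= 0)) {
    stop("`viewing_distance_cm` must be positive.", call. = FALSE)
  }
  viewing_distance_cm * tan(angle_deg * pi / 180)
}

#' Minimum-jerk position profile
#'
#' Normalised position of the classic minimum-jerk point-to-point movement,
#' `m(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`, clamped to \[0, 1\] outside the
#' movement interval. Its speed peaks at `tau = 0.5` with normalised value
#' 1.875, so a movement of amplitude `D` and duration `T` has peak speed
#' `1.875 * D / T`.
#'
#' @param tau Normalised time (0 = movement onset, 1 = movement end).
#' @return Normalised position in \[0, 1\].
#' @export
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Reach progress profile with a configurable peak-velocity time
#'
#' Smooth unit movement profile built from two half minimum-jerk segments
#' joined at the peak-velocity instant `tau = peak_frac`. The acceleration
#' phase is the first half of a minimum-jerk movement of duration
#' `2 * peak_frac` and amplitude `2 * peak_frac`; the deceleration phase is the
#' mirrored second half. Position and velocity are continuous at the junction
#' (acceleration of a minimum-jerk profile is zero at mid-movement), the peak
#' speed is `1.875 * D / T` independently of `peak_frac`, and `peak_frac = 0.5`
#' reduces exactly to [min_jerk()]. This yields asymmetric
#' acceleration/deceleration phases, as observed in human reaches, while
#' keeping closed-form landmarks.
#'
#' @param tau Normalised time in \[0, 1\] (clamped outside).
#' @param peak_frac Fraction of movement time at which speed peaks, in (0, 1).
#' @return Normalised position in \[0, 1\].
#' @export
reach_profile <- function(tau, peak_frac = 0.5) {
  if (peak_frac <= 0 || peak_frac >= 1) {
    stop("`peak_frac` must be in (0, 1).", call. = FALSE)
  }
  tau <- pmin(pmax(tau, 0), 1)
  a <- peak_frac
  accel <- 2 * a * min_jerk(tau / (2 * a))
  decel <- 1 - 2 * (1 - a) * (1 - min_jerk((tau - (2 * a - 1)) / (2 * (1 - a))))
  ifelse(tau <= a, accel, decel)
}

#' On-screen target position for a trial condition
#'
#' The initial target sits on the vertical screen midline, elevated above the
#' fixation point; perturbed targets are displaced laterally by the
#' perturbation eccentricity. Angles are converted to cm with exact arctangent
#' geometry at the viewing distance. The screen plane is `z = 0`, x positive
#' rightward, y positive upward, fixation at the origin.
#'
#' @param direction `"none"` (initial/static target), `"left"` or `"right"`.
#' @param eccentricity_deg Lateral displacement of perturbed targets from the
#'   midline, degrees of visual angle. Default 10.
#' @param elevation_deg Elevation of the target above fixation, degrees.
#'   Default 4.5.
#' @inheritParams cm_to_dva
#' @return Named numeric vector `c(x, y)` in cm.
#' @export
target_position <- function(direction = c("none", "left", "right"),
                            eccentricity_deg = 10,
                            elevation_deg = 4.5,
                            viewing_distance_cm = 40) {
  direction <- match.arg(direction)
  sgn <- switch(direction, none = 0, left = -1, right = 1)
  c(
    x = sgn * dva_to_cm(eccentricity_deg, viewing_distance_cm),
    y = dva_to_cm(elevation_deg, viewing_distance_cm)
  )
}
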