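#' Construct a single reach trial
#'
#' A trial couples the tracker sample stream with the behavioural events and
#' condition labels of one double-step pointing movement. Times are absolute
#' seconds on the trial clock (0 = fixation onset); positions are cm in the
#' screen-centred frame (x rightward, y upward, z distance from the screen,
#' screen plane at z = 0).
#'
#' The constructor enforces structural validity only (required fields,
#' strictly increasing sample times, known condition labels). Behavioural
#' invariants — reach onset after target onset, a recorded touch, gap-free
#' sampling — are the business of [screen_error_trials()], since violating
#' them is precisely what marks an error trial in real recordings.
#'
#' @param participant Participant identifier (character scalar).
#' @param group Group label, e.g. `"younger"` or `"older"`.
#' @param block,trial Integer block and trial indices.
#' @param condition Perturbation time condition: `"none"`, `"0"` or `"200"`
#'   (ms after reach onset).
#' @param direction Perturbation direction: `"none"`, `"left"` or `"right"`.
#' @param target_onset_s,reach_onset_s,touch_s Event times in s; `touch_s` may
#'   be `NA` when the touchscreen failed to register a response.
#' @param perturbation_s Absolute perturbation time in s (`NA` on static
#'   trials).
#' @param touch_x_cm,touch_y_cm Touch location on the screen, cm (may be `NA`).
#' @param samples Data frame with columns `t_s`, `x_cm`, `y_cm`, `z_cm`,
#'   ordered by strictly increasing `t_s`.
#' @param sampling_rate_hz Nominal tracker rate, Hz.
#' @return An object of class `ds_trial`.
#' @export
reach_trial <- function(participant, group, block, trial,
                        condition = c("none", "0", "200"),
                        direction = c("none", "left", "right"),
                        target_onset_s, reach_onset_s, touch_s,
                        perturbation_s = NA_real_,
                        touch_x_cm = NA_real_, touch_y_cm = NA_real_,
                        samples, sampling_rate_hz = 240) {
  condition <- match.arg(as.character(condition), c("none", "0", "200"))
  direction <- match.arg(direction)
  if ((condition == "none") != (direction == "none")) {
    stop("`condition` and `direction` must be 'none' together.", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  needed <- c("t_s", "x_cm", "y_cm", "z_cm")
  if (!all(needed %in% names(samples))) {
    stop(
      "`samples` must have columns ", paste(needed, collapse = ", "), ".",
      call. = FALSE
    )
  }
  if (nrow(samples) > 1 && any(diff(samples$t_s) <= 0)) {
    stop(
      sprintf(
        "Sample times must be strictly increasing (participant %s block %s trial %s).",
        participant, block, trial
      ),
      call. = FALSE
    )
  }
  structure(
    list(
      participant = as.character(participant),
      group = as.character(group),
      block = as.integer(block),
      trial = as.integer(trial),
      condition = condition,
      direction = direction,
      target_onset_s = target_onset_s,
      reach_onset_s = reach_onset_s,
      perturbation_s = perturbation_s,
      touch_s = touch_s,
      touch_x_cm = touch_x_cm,
      touch_y_cm = touch_y_cm,
      samples = samples[needed],
      sampling_rate_hz = sampling_rate_hz
    ),
    class = "ds_trial"
  )
}

#' @export
print.ds_trial <- function(x, ...) {
  cat(sprintf(
    "<ds_trial> %s/%s block %d trial %d | %s%s | %d samples @ %g Hz\n",
    x$participant, x$group, x$block, x$trial,
    if (x$condition == "none") "static" else paste0(x$condition, " ms "),
    if (x$direction == "none") "" else x$direction,
    nrow(x$samples), x$sampling_rate_hz
  ))
  invisible(x)
}

#' Is a trial perturbed?
#'
#' @param trial A `ds_trial`.
#' @return `TRUE` for perturbed (double-step) trials.
#' @export
is_perturbed <- function(trial) {
  stopifnot(inherits(trial, "ds_trial"))
  trial$condition != "none"
}

#' Construct a session of reach trials
#'
#' A session is an ordered collection of [reach_trial()] objects that share a
#' sampling rate, possibly spanning several participants.
#'
#' @param trials List of `ds_trial` objects.
#' @param sampling_rate_hz Common tracker rate, Hz.
#' @param metadata Optional named list of apparatus metadata.
#' @return An object of class `ds_session`.
#' @export
reach_session <- function(trials, sampling_rate_hz = 240, metadata = list()) {
  stopifnot(is.list(trials))
  for (tr in trials) {
    if (!inherits(tr, "ds_trial")) {
      stop("All elements of `trials` must be ds_trial objects.", call. = FALSE)
    }
    if (!isTRUE(all.equal(tr$sampling_rate_hz, sampling_rate_hz))) {
      stop("All trials must share the session sampling rate.", call. = FALSE)
    }
  }
  structure(
    list(
      trials = trials,
      sampling_rate_hz = sampling_rate_hz,
      metadata = metadata
    ),
    class = "ds_session"
  )
}

#' @export
print.ds_session <- function(x, ...) {
  info <- session_info(x)
  cat(sprintf(
    "<ds_session> %d trials, %d participant(s) @ %g Hz\n",
    length(x$trials), length(unique(info$participant)), x$sampling_rate_hz
  ))
  if (length(x$trials)) {
    print(dplyr::count(info, .data$group, .data$condition, .data$direction))
  }
  invisible(x)
}

#' @export
length.ds_session <- function(x) length(x$trials)

#' Per-trial label table of a session
#'
#' @param session A `ds_session`.
#' @return A tibble with one row per trial: participant, group, block, trial,
#'   condition, direction and event times.
#' @export
session_info <- function(session) {
  stopifnot(inherits(session, "ds_session"))
  purrr::map_dfr(session$trials, function(tr) {
    tibble::tibble(
      participant = tr$participant,
      group = tr$group,
      block = tr$block,
      trial = tr$trial,
      condition = tr$condition,
      direction = tr$direction,
      target_onset_s = tr$target_onset_s,
      reach_onset_s = tr$reach_onset_s,
      perturbation_s = tr$perturbation_s,
      touch_s = tr$touch_s,
      touch_x_cm = tr$touch_x_cm,
      touch_y_cm = tr$touch_y_cm,
      n_samples = nrow(tr$samples)
    )
  })
}

#' Samples of a trial restricted to the movement window
#'
#' Returns the sample rows from reach onset to touch (inclusive); used by the
#' path-linearity and envelope computations, which are defined over the
#' in-flight portion of the trajectory.
#'
#' @param trial A `ds_trial`.
#' @return A tibble of samples.
#' @export
movement_samples <- function(trial) {
  stopifnot(inherits(trial, "ds_trial"))
  s <- trial$samples
  hi <- if (is.na(trial$touch_s)) Inf else trial$touch_s
  eps <- 0.5 / trial$sampling_rate_hz
  s[s$t_s >= trial$reach_onset_s - eps & s$t_s <= hi + eps, , drop = FALSE]
}
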