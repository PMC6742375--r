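#' Build the non-perturbed trajectory envelope
#'
#' Averages the horizontal (x) traces of non-perturbed trials from one
#' grouping unit on the common sample grid aligned at reach onset, and
#' computes the per-sample cross-trial mean, sample SD and support count. The
#' detection band is mean +/- `k` SD. Trials drop out of the average as they
#' end, so the support count is non-increasing; the envelope is kept up to the
#' last sample with at least `min_support` trials in flight, and the
#' detector holds the final mean and SD beyond that point.
#'
#' @param trials List of non-perturbed [reach_trial()] objects (at least
#'   `min_support` of them), cleaned and filtered.
#' @param k SD multiplier of the band (default 1.5).
#' @param min_support Minimum trials both overall and per sample (default 10).
#' @param grouping Label of the grouping unit, used in messages (e.g.
#'   `"P01 block 2"`).
#' @return An object of class `ds_envelope`: tibble `bands` with columns
#'   `sample` (index from reach onset), `time_ms`, `mean_x_cm`, `sd_x_cm`,
#'   `n`, plus the parameters.
#' @export
build_envelope <- function(trials, k = 1.5, min_support = 10, grouping = "unit") {
  if (length(trials) < min_support) {
    stop(
      sprintf(
        "Envelope for %s needs >= %d non-perturbed trials, got %d.",
        grouping, min_support, length(trials)
      ),
      call. = FALSE
    )
  }
  for (tr in trials) {
    stopifnot(inherits(tr, "ds_trial"))
    if (is_perturbed(tr)) {
      stop(
        sprintf("Envelope for %s: perturbed trials are not allowed.", grouping),
        call. = FALSE
      )
    }
  }
  fs <- trials[[1]]$sampling_rate_hz
  aligned <- lapply(trials, function(tr) {
    s <- movement_samples(tr)
    j <- round((s$t_s - tr$reach_onset_s) * fs)
    ok <- j >= 0
    list(j = j[ok], x = s$x_cm[ok])
  })
  max_j <- max(vapply(aligned, function(a) max(a$j), numeric(1)))
  mat <- matrix(NA_real_, nrow = length(aligned), ncol = max_j + 1)
  for (i in seq_along(aligned)) {
    mat[i, aligned[[i]]$j + 1] <- aligned[[i]]$x
  }
  n <- colSums(!is.na(mat))
  mean_x <- colMeans(mat, na.rm = TRUE)
  sd_x <- apply(mat, 2, stats::sd, na.rm = TRUE)
  last <- max(which(n >= min_support))
  bands <- tibble::tibble(
    sample = 0:(last - 1),
    time_ms = (0:(last - 1)) / fs * 1000,
    mean_x_cm = mean_x[1:last],
    sd_x_cm = sd_x[1:last],
    n = n[1:last]
  )
  structure(
    list(
      bands = bands, k = k, min_support = min_support,
      sampling_rate_hz = fs, grouping = grouping, n_trials = length(trials)
    ),
    class = "ds_envelope"
  )
}

#' @export
print.ds_envelope <- function(x, ...) {
  cat(sprintf(
    "<ds_envelope> %s: %d trials, +/-%g SD band over %d samples (%.0f ms)\n",
    x$grouping, x$n_trials, x$k, nrow(x$bands),
    max(x$bands$time_ms)
  ))
  invisible(x)
}

envelope_lookup <- function(envelope, j) {
  # hold the final mean/SD beyond envelope support
  jj <- pmin(pmax(j, 0), nrow(envelope$bands) - 1) + 1
  envelope$bands[jj, c("mean_x_cm", "sd_x_cm")]
}

#' Detect an online correction and estimate its latency
#'
#' Implements the envelope method: a corrective response on a perturbed trial
#' is the first point at which the horizontal hand position exceeds the
#' mean +/- k SD band of the non-perturbed trajectories, on the side of the
#' perturbation, no earlier than `min_delay_ms` after the perturbation (the
#' minimum visuomotor delay), and sustained for `sustain` consecutive
#' samples. The correction latency is the time of that point minus the
#' perturbation time; a trajectory already outside the band when the scan
#' opens is assigned the floor latency `min_delay_ms` exactly. If no
#' qualifying excursion occurs before touch, no response is recorded for the
#' trial.
#'
#' Excursions beyond the band on the side opposite the perturbation are not
#' counted as corrections (they would be overshoot or noise) but are flagged
#' in the output.
#'
#' @param trial A perturbed [reach_trial()], cleaned and filtered.
#' @param envelope A [build_envelope()] result from the trial's grouping unit.
#' @param min_delay_ms Minimum visuomotor delay in ms (default 80).
#' @param sustain Number of consecutive samples the trace must stay outside
#'   the band (default 3, about 12.5 ms at 240 Hz; 1 reproduces the bare
#'   threshold rule).
#' @param k SD multiplier; defaults to the envelope's `k`.
#' @return A one-row tibble: `detected`, `correction_latency_ms` (`NA` when
#'   undetected), `opposite_crossing` (sustained excursion away from the
#'   perturbation), and the trial identifiers.
#' @export
detect_correction <- function(trial, envelope, min_delay_ms = 80, sustain = 3,
                              k = NULL) {
  stopifnot(inherits(trial, "ds_trial"), inherits(envelope, "ds_envelope"))
  if (!is_perturbed(trial) || is.na(trial$perturbation_s)) {
    stop("Correction detection requires a perturbed trial with a known perturbation time.",
      call. = FALSE
    )
  }
  if (nrow(envelope$bands) == 0) {
    stop(
      sprintf("Envelope for %s is undefined over the scan window.", envelope$grouping),
      call. = FALSE
    )
  }
  if (is.null(k)) k <- envelope$k
  fs <- trial$sampling_rate_hz
  s <- movement_samples(trial)
  j <- round((s$t_s - trial$reach_onset_s) * fs)
  ok <- j >= 0
  j <- j[ok]
  t <- s$t_s[ok]
  x <- s$x_cm[ok]
  side <- if (trial$direction == "right") 1 else -1
  bands <- envelope_lookup(envelope, j)
  dev <- side * (x - bands$mean_x_cm)
  outside <- dev > k * bands$sd_x_cm
  opposite <- -dev > k * bands$sd_x_cm

  eps <- 0.5 / fs
  scan <- t >= trial$perturbation_s - eps
  trial_id <- trial$trial
  cond <- trial$condition
  dir_ <- trial$direction
  res <- tibble::tibble(
    participant = trial$participant, group = trial$group,
    block = trial$block, trial = trial_id,
    condition = cond, direction = dir_,
    detected = FALSE, correction_latency_ms = NA_real_,
    opposite_crossing = FALSE
  )
  if (!any(scan)) {
    return(res)
  }
  first_sustained <- function(mask, times) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    open_ms <- trial$perturbation_s + min_delay_ms / 1000
    for (i in seq_along(r$values)) {
      if (!r$values[i] || r$lengths[i] < sustain) next
      # the excursion must still be (or become) active once the scan opens
      if (times[ends[i]] < open_ms - eps) next
      return(times[starts[i]])
    }
    NA_real_
  }
  t_on <- first_sustained(outside[scan], t[scan])
  if (!is.na(t_on)) {
    res$detected <- TRUE
    res$correction_latency_ms <- max(min_delay_ms, (t_on - trial$perturbation_s) * 1000)
  }
  res$opposite_crossing <- !is.na(first_sustained(opposite[scan], t[scan]))
  res
}

#' Path linearity and maximum path offset of a reach
#'
#' Atkeson-Hollerbach linearity of the sampled hand path: `B` is the
#' Euclidean distance between the start and end points, `A` the maximum
#' perpendicular (normal) distance of any sample to the infinite line through
#' them, and `L = A / B` the dimensionless linearity index — `L = 0` for a
#' perfectly straight path. `A` is the maximum path offset (MPO) in cm; the
#' index of its sample is returned for [mpo_latency()]. The distance is 3D by
#' default, with a horizontal-plane option.
#'
#' @param samples Tibble of position samples from reach onset to touch (at
#'   least 3 rows).
#' @param dims Coordinate columns used for the distance computation.
#' @return A list: `L`, `A_cm`, `B_cm`, `argmax` (row index of the MPO,
#'   earliest on ties), `degenerate` (`TRUE` when start and end coincide, in
#'   which case the measures are `NA`).
#' @examples
#' p <- tibble::tibble(x_cm = c(0, 5, 10), y_cm = c(0, 5, 0), z_cm = 0)
#' path_linearity(p)  # A = 5, B = 10, L = 0.5
#' @export
path_linearity <- function(samples, dims = c("x_cm", "y_cm", "z_cm")) {
  stopifnot(all(dims %in% names(samples)))
  p <- as.matrix(samples[dims])
  n <- nrow(p)
  if (n < 3) stop("Need at least 3 samples.", call. = FALSE)
  s <- p[1, ]
  e <- p[n, ]
  B <- sqrt(sum((e - s)^2))
  if (B < 1e-12) {
    return(list(
      L = NA_real_, A_cm = NA_real_, B_cm = 0,
      argmax = NA_integer_, degenerate = TRUE
    ))
  }
  d <- (e - s) / B
  rel <- sweep(p, 2, s)
  proj <- as.vector(rel %*% d)
  perp2 <- pmax(rowSums(rel^2) - proj^2, 0)
  argmax <- which.max(perp2)
  A <- sqrt(perp2[argmax])
  list(L = A / B, A_cm = A, B_cm = B, argmax = as.integer(argmax), degenerate = FALSE)
}

#' Latency of the maximum path offset
#'
#' Time of the sample at which the hand path is furthest from the straight
#' start-end line, measured from the perturbation onset (the same clock as
#' the correction latency). Defined only for perturbed trials: the MPO
#' latency is an envelope-free estimate of when the corrective response
#' peaks.
#'
#' @param trial A perturbed [reach_trial()].
#' @param argmax Row index of the MPO within [movement_samples()] rows; when
#'   `NULL` it is recomputed via [path_linearity()].
#' @param dims Coordinates for the recomputation.
#' @return Latency in ms from perturbation onset.
#' @export
mpo_latency <- function(trial, argmax = NULL, dims = c("x_cm", "y_cm", "z_cm")) {
  stopifnot(inherits(trial, "ds_trial"))
  if (!is_perturbed(trial) || is.na(trial$perturbation_s)) {
    stop("MPO latency is undefined for non-perturbed trials.", call. = FALSE)
  }
  s <- movement_samples(trial)
  if (is.null(argmax)) {
    pl <- path_linearity(s, dims)
    if (pl$degenerate) stop("Degenerate path (start = end).", call. = FALSE)
    argmax <- pl$argmax
  }
  (s$t_s[argmax] - trial$perturbation_s) * 1000
}

envelope_key <- function(participant, block, grouping) {
  if (grouping == "participant_block") {
    paste0(participant, ".block", block)
  } else {
    as.character(participant)
  }
}

#' Build envelopes for every grouping unit of a session
#'
#' Splits the session's cleaned non-perturbed trials by grouping unit
#' (participant x block by default, following the convention of averaging
#' within a block; or pooled per participant) and builds one envelope per
#' unit.
#'
#' @param session A [reach_session()], cleaned and filtered.
#' @param grouping `"participant_block"` or `"participant"`.
#' @inheritParams build_envelope
#' @return Named list of [build_envelope()] objects.
#' @export
build_envelopes <- function(session, grouping = c("participant_block", "participant"),
                            k = 1.5, min_support = 10) {
  stopifnot(inherits(session, "ds_session"))
  grouping <- match.arg(grouping)
  static <- Filter(Negate(is_perturbed), session$trials)
  if (!length(static)) {
    stop("Session has no non-perturbed trials; cannot build envelopes.", call. = FALSE)
  }
  keys <- vapply(
    static,
    function(tr) envelope_key(tr$participant, tr$block, grouping),
    character(1)
  )
  out <- lapply(split(static, keys), function(trs) {
    build_envelope(trs,
      k = k, min_support = min_support,
      grouping = envelope_key(trs[[1]]$participant, trs[[1]]$block, grouping)
    )
  })
  out
}

#' Correction detection and path measures for every perturbed trial
#'
#' Runs [detect_correction()], [path_linearity()] and [mpo_latency()] on each
#' perturbed trial of a session, using the envelope of the trial's grouping
#' unit.
#'
#' @param session A [reach_session()], cleaned and filtered.
#' @param envelopes Named list from [build_envelopes()].
#' @param grouping Grouping used to build the envelopes.
#' @param min_delay_ms,sustain Passed to [detect_correction()].
#' @param dims Coordinates for the path measures.
#' @return A tibble, one row per perturbed trial: detection flag, correction
#'   latency, `L`, `A_cm` (MPO), `B_cm`, MPO latency, opposite-crossing flag.
#' @export
correction_results <- function(session, envelopes,
                               grouping = c("participant_block", "participant"),
                               min_delay_ms = 80, sustain = 3,
                               dims = c("x_cm", "y_cm", "z_cm")) {
  stopifnot(inherits(session, "ds_session"))
  grouping <- match.arg(grouping)
  perturbed <- Filter(is_perturbed, session$trials)
  purrr::map_dfr(perturbed, function(tr) {
    key <- envelope_key(tr$participant, tr$block, grouping)
    env <- envelopes[[key]]
    if (is.null(env)) {
      stop(
        sprintf("No envelope available for grouping unit %s.", key),
        call. = FALSE
      )
    }
    det <- detect_correction(tr, env, min_delay_ms = min_delay_ms, sustain = sustain)
    s <- movement_samples(tr)
    pl <- path_linearity(s, dims)
    det$L <- pl$L
    det$mpo_cm <- pl$A_cm
    det$path_length_cm <- pl$B_cm
    det$mpo_latency_ms <- if (pl$degenerate) NA_real_ else mpo_latency(tr, pl$argmax, dims)
    det
  })
}

#' Correction-frequency table
#'
#' Percentage of perturbed trials on which a correction was detected, per
#' group x perturbation time x direction cell. Cells without any perturbed
#' trial are reported as missing (`NA`), never as zero.
#'
#' @param results Tibble from [correction_results()].
#' @return A tibble with columns `group`, `condition`, `direction`,
#'   `n_trials`, `n_detected`, `pct_corrected`.
#' @export
correction_frequency <- function(results) {
  stopifnot(all(c("group", "condition", "direction", "detected") %in% names(results)))
  tab <- results |>
    dplyr::group_by(.data$group, .data$condition, .data$direction) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_detected = sum(.data$detected),
      pct_corrected = 100 * .data$n_detected / .data$n_trials,
      .groups = "drop"
    )
  tidyr::complete(
    tab,
    group = unique(results$group),
    condition = unique(results$condition),
    direction = unique(results$direction)
  ) |>
    dplyr::arrange(.data$group, .data$condition, .data$direction)
}
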