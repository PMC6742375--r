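#' Screen a session for apparatus and participant error trials
#'
#' First-pass cleaning, mirroring the visual inspection stage of trajectory
#' studies. A trial is removed when (reasons as reported):
#' \describe{
#'   \item{`missing_touch`}{no touch response was registered;}
#'   \item{`premature_start`}{reach onset precedes target onset;}
#'   \item{`sample_gap`}{more than `max_gap_samples` consecutive samples are
#'     missing from the stream;}
#'   \item{`zero_length`}{the trajectory has fewer than 3 samples or zero
#'     start-to-end extent.}
#' }
#' Screening never raises; it returns the retained session together with an
#' itemised removal table and a per-participant/condition [cleaning_report()].
#'
#' @param session A [reach_session()].
#' @param max_gap_samples Largest tolerated run of missing samples (default 3).
#' @return A list: `session` (retained trials), `removals` (tibble:
#'   participant, block, trial, reason), `report` (tibble from
#'   [cleaning_report()], stage `"error_screen"`).
#' @export
screen_error_trials <- function(session, max_gap_samples = 3) {
  stopifnot(inherits(session, "ds_session"))
  fs <- session$sampling_rate_hz
  reasons <- purrr::map_chr(session$trials, function(tr) {
    s <- tr$samples
    if (is.na(tr$touch_s) || is.na(tr$touch_x_cm)) {
      return("missing_touch")
    }
    if (!is.na(tr$reach_onset_s) && tr$reach_onset_s < tr$target_onset_s) {
      return("premature_start")
    }
    if (nrow(s) >= 2) {
      gaps <- round(diff(s$t_s) * fs) - 1
      if (any(gaps > max_gap_samples)) {
        return("sample_gap")
      }
    }
    if (nrow(s) < 3) {
      return("zero_length")
    }
    p0 <- unlist(s[1, c("x_cm", "y_cm", "z_cm")])
    p1 <- unlist(s[nrow(s), c("x_cm", "y_cm", "z_cm")])
    if (sqrt(sum((p1 - p0)^2)) < 1e-12) {
      return("zero_length")
    }
    NA_character_
  })
  keep <- is.na(reasons)
  info <- session_info(session)
  removals <- dplyr::mutate(
    info[!keep, c("participant", "group", "block", "trial", "condition", "direction")],
    reason = reasons[!keep]
  )
  list(
    session = reach_session(session$trials[keep], fs, session$metadata),
    removals = removals,
    report = cleaning_report(info, keep, stage = "error_screen")
  )
}

#' Flag outliers with the median-absolute-deviation rule
#'
#' Robust outlier detection for per-trial dependent measures: a value `v` is
#' flagged when `|v - median| / (1.4826 * MAD) > threshold`, where `MAD` is
#' the raw median absolute deviation and 1.4826 the Gaussian consistency
#' constant (so the statistic reads as a robust z-score). When `MAD = 0`
#' (more than half the values identical) any value different from the median
#' is flagged. With fewer than 4 values nothing is flagged and a warning is
#' issued.
#'
#' @param values Numeric vector of per-trial measures.
#' @param threshold Robust z-score multiplier (default 3, a conservative
#'   choice within the conventional 2.5-3 range).
#' @return Logical vector: `TRUE` marks an outlier. `NA` values are never
#'   flagged.
#' @examples
#' mad_outliers(c(2, 3, 4, 100))   # flags 100
#' mad_outliers(c(1, 2, 3, 4, 5))  # none
#' @export
mad_outliers <- function(values, threshold = 3) {
  stopifnot(is.numeric(values))
  n_ok <- sum(!is.na(values))
  if (n_ok < 4) {
    warning("Fewer than 4 values; no outliers flagged.", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  med <- stats::median(values, na.rm = TRUE)
  scale <- stats::mad(values, na.rm = TRUE) # includes the 1.4826 constant
  tol <- 1e-8 * max(1, abs(med))
  if (scale <= tol) {
    # (near-)zero spread: flag anything off the median beyond numerical noise
    out <- abs(values - med) > tol
  } else {
    out <- abs(values - med) / scale > threshold
  }
  out & !is.na(out)
}

#' Remove MAD outlier trials from a dependent-variable table
#'
#' Applies [mad_outliers()] to each requested measure within each grouping
#' cell (by default participant x condition x direction, the unit at which
#' performance outliers are defined) and removes trials flagged on any
#' measure.
#'
#' @param dv_table Per-trial tibble, e.g. from [kinematics_table()].
#' @param dvs Character vector of measure columns to screen.
#' @param by Grouping columns defining a screening cell.
#' @param threshold Passed to [mad_outliers()].
#' @return A list: `dv_table` (retained rows), `removals` (flagged rows with
#'   a `reason` column), `report` (tibble from [cleaning_report()], stage
#'   `"mad_outliers"`).
#' @export
screen_outlier_trials <- function(dv_table,
                                  dvs = c(
                                    "reach_latency_ms", "reach_duration_ms",
                                    "peak_velocity_cms"
                                  ),
                                  by = c("participant", "condition", "direction"),
                                  threshold = 3) {
  stopifnot(all(by %in% names(dv_table)))
  dvs <- intersect(dvs, names(dv_table))
  if (!length(dvs)) stop("No requested measure columns present.", call. = FALSE)
  flag <- rep(FALSE, nrow(dv_table))
  cells <- split(seq_len(nrow(dv_table)), interaction(dv_table[by], drop = TRUE))
  for (ii in cells) {
    for (dv in dvs) {
      flag[ii] <- flag[ii] | mad_outliers(dv_table[[dv]][ii], threshold = threshold)
    }
  }
  keep <- !flag
  removals <- dplyr::mutate(dv_table[!keep, , drop = FALSE], reason = "mad_outlier")
  list(
    dv_table = dv_table[keep, , drop = FALSE],
    removals = removals,
    report = cleaning_report(dv_table, keep, stage = "mad_outliers")
  )
}

#' Tabulate removed and retained trial counts
#'
#' Summarises a cleaning stage per participant x condition x direction:
#' input, removed and retained counts plus the removed fraction. By
#' construction `removed + retained = input` in every row.
#'
#' @param info Per-trial tibble with `participant`, `condition`, `direction`.
#' @param keep Logical vector, `TRUE` for retained trials.
#' @param stage Stage label stored in the report.
#' @return A tibble with one row per cell.
#' @export
cleaning_report <- function(info, keep, stage = "cleaning") {
  stopifnot(nrow(info) == length(keep))
  info |>
    dplyr::mutate(.keep_flag = keep) |>
    dplyr::group_by(.data$participant, .data$condition, .data$direction) |>
    dplyr::summarise(
      n_input = dplyr::n(),
      n_removed = sum(!.data$.keep_flag),
      n_retained = sum(.data$.keep_flag),
      fraction_removed = .data$n_removed / .data$n_input,
      .groups = "drop"
    ) |>
    dplyr::mutate(stage = stage, .before = 1)
}
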