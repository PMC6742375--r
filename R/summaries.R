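#' Percent difference between two scores
#'
#' Unsigned difference divided by the mean of the two scores, times 100,
#' rounded to the nearest whole number — the descriptive effect measure used
#' for group comparisons. Symmetric in its arguments and bounded by 200 for
#' same-signed inputs.
#'
#' @param a,b Numeric vectors (recycled).
#' @return Integer percent; `NA` with a warning where `a + b = 0`
#'   (undefined).
#' @examples
#' percent_difference(532.3, 496.3)  # 7
#' @export
percent_difference <- function(a, b) {
  undef <- (a + b) == 0
  if (any(undef, na.rm = TRUE)) {
    warning("percent_difference undefined where a + b = 0; returning NA.", call. = FALSE)
  }
  out <- round(abs(a - b) / ((a + b) / 2) * 100)
  out[undef] <- NA_real_
  out
}

#' Two-stage condition summaries of per-trial measures
#'
#' Aggregates a per-trial dependent-variable table into condition x group x
#' direction cell statistics. Aggregation is two-stage by default: trials are
#' first averaged within participant, then cells are summarised over
#' participant means — the appropriate weighting when cleaning removes
#' unequal numbers of trials per participant. Pooled (single-stage)
#' aggregation over raw trials is available via `two_stage = FALSE`. Rows are
#' deterministically ordered; summaries are invariant to trial order and
#' participant relabelling.
#'
#' @param dv_table Per-trial tibble (e.g. [kinematics_table()], optionally
#'   joined with correction results).
#' @param dvs Measure columns to summarise; defaults to all numeric columns
#'   apart from identifiers.
#' @param two_stage Participant-mean aggregation (default) or pooled trials.
#' @return A tibble in long format: one row per (group, condition, direction,
#'   measure) with `mean`, `sd`, `n` (participants for two-stage, trials for
#'   pooled), `n_trials`, `min`, `max`.
#' @export
condition_summary <- function(dv_table, dvs = NULL, two_stage = TRUE) {
  ids <- c("participant", "group", "block", "trial", "condition", "direction")
  stopifnot(all(c("participant", "group", "condition", "direction") %in% names(dv_table)))
  if (is.null(dvs)) {
    dvs <- setdiff(names(dv_table)[vapply(dv_table, is.numeric, logical(1))], ids)
  }
  long <- dv_table |>
    dplyr::select(dplyr::all_of(c(
      "participant", "group", "condition", "direction", dvs
    ))) |>
    tidyr::pivot_longer(dplyr::all_of(dvs), names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  if (two_stage) {
    by_participant <- long |>
      dplyr::group_by(
        .data$group, .data$condition, .data$direction,
        .data$participant, .data$measure
      ) |>
      dplyr::summarise(
        value = mean(.data$value),
        n_trials = dplyr::n(),
        .groups = "drop"
      )
    out <- by_participant |>
      dplyr::group_by(.data$group, .data$condition, .data$direction, .data$measure) |>
      dplyr::summarise(
        mean = mean(.data$value),
        sd = stats::sd(.data$value),
        n = dplyr::n(),
        n_trials = sum(.data$n_trials),
        min = min(.data$value),
        max = max(.data$value),
        .groups = "drop"
      )
  } else {
    out <- long |>
      dplyr::group_by(.data$group, .data$condition, .data$direction, .data$measure) |>
      dplyr::summarise(
        mean = mean(.data$value),
        sd = stats::sd(.data$value),
        n = dplyr::n(),
        n_trials = dplyr::n(),
        min = min(.data$value),
        max = max(.data$value),
        .groups = "drop"
      )
  }
  dplyr::arrange(
    out, .data$measure, .data$group, .data$condition, .data$direction
  )
}

#' Participant-level long-format export
#'
#' Per-participant cell means of every measure, the table a mixed-model
#' analysis in an external statistics environment would consume (one row per
#' participant x condition x direction x measure).
#'
#' @inheritParams condition_summary
#' @return A tibble with `participant`, `group`, `condition`, `direction`,
#'   `measure`, `mean`, `n_trials`.
#' @export
participant_means <- function(dv_table, dvs = NULL) {
  ids <- c("participant", "group", "block", "trial", "condition", "direction")
  if (is.null(dvs)) {
    dvs <- setdiff(names(dv_table)[vapply(dv_table, is.numeric, logical(1))], ids)
  }
  dv_table |>
    dplyr::select(dplyr::all_of(c(
      "participant", "group", "condition", "direction", dvs
    ))) |>
    tidyr::pivot_longer(dplyr::all_of(dvs), names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(
      .data$participant, .data$group, .data$condition,
      .data$direction, .data$measure
    ) |>
    dplyr::summarise(
      mean = mean(.data$value),
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(
      .data$measure, .data$group, .data$participant,
      .data$condition, .data$direction
    )
}
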