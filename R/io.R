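#' Write a session to long-format CSV files
#'
#' Writes two plain-text files: `<prefix>_samples.csv`, one row per tracker
#' sample (participant, group, block, trial, condition_ms, direction, t_s,
#' x_cm, y_cm, z_cm), and `<prefix>_events.csv`, one row per trial with the
#' behavioural events, touch location and sampling rate. The pair
#' round-trips through [read_session()] with numeric agreement to at least
#' 1e-9.
#'
#' @param session A [reach_session()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"session"`).
#' @return Invisibly, the two file paths.
#' @export
write_session <- function(session, dir, prefix = "session") {
  stopifnot(inherits(session, "ds_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- purrr::map_dfr(session$trials, function(tr) {
    dplyr::mutate(
      tr$samples,
      participant = tr$participant, group = tr$group,
      block = tr$block, trial = tr$trial,
      condition_ms = tr$condition, direction = tr$direction,
      .before = 1
    )
  })
  events <- session_info(session)
  events <- dplyr::rename(events, condition_ms = "condition")
  events$sampling_rate_hz <- session$sampling_rate_hz
  events$n_samples <- NULL
  sp <- file.path(dir, paste0(prefix, "_samples.csv"))
  ep <- file.path(dir, paste0(prefix, "_events.csv"))
  readr::write_csv(samples, sp)
  readr::write_csv(events, ep)
  invisible(c(samples = sp, events = ep))
}

sample_cols <- c(
  "participant", "group", "block", "trial", "condition_ms", "direction",
  "t_s", "x_cm", "y_cm", "z_cm"
)
event_cols <- c(
  "participant", "group", "block", "trial", "condition_ms", "direction",
  "target_onset_s", "reach_onset_s", "perturbation_s", "touch_s",
  "touch_x_cm", "touch_y_cm", "sampling_rate_hz"
)

#' Read a session from long-format CSV files
#'
#' Counterpart of [write_session()]. Trials whose sample times are not
#' strictly increasing are rejected individually with a diagnostic naming the
#' trial; the remaining trials load normally. Empty files yield an empty
#' session with a warning.
#'
#' @param dir Directory containing the files.
#' @param prefix File name prefix used at write time.
#' @return A [reach_session()].
#' @export
read_session <- function(dir, prefix = "session") {
  sp <- file.path(dir, paste0(prefix, "_samples.csv"))
  ep <- file.path(dir, paste0(prefix, "_events.csv"))
  for (p in c(sp, ep)) {
    if (!file.exists(p)) stop(sprintf("File not found: %s", p), call. = FALSE)
  }
  samples <- readr::read_csv(sp, show_col_types = FALSE, progress = FALSE)
  events <- readr::read_csv(ep, show_col_types = FALSE, progress = FALSE)
  if (nrow(events) == 0 || nrow(samples) == 0) {
    warning("Empty session files; returning an empty session.", call. = FALSE)
    return(reach_session(list(), sampling_rate_hz = 240))
  }
  miss_s <- setdiff(sample_cols, names(samples))
  miss_e <- setdiff(event_cols, names(events))
  if (length(miss_s) || length(miss_e)) {
    stop(
      "Missing columns: ",
      paste(c(miss_s, miss_e), collapse = ", "), ".",
      call. = FALSE
    )
  }
  fs <- unique(events$sampling_rate_hz)
  if (length(fs) != 1) {
    stop("All trials must share one sampling rate.", call. = FALSE)
  }
  samples <- dplyr::group_by(samples, .data$participant, .data$block, .data$trial)
  sample_groups <- dplyr::group_split(samples)
  keys <- dplyr::group_keys(samples)
  key_id <- paste(keys$participant, keys$block, keys$trial)
  ev_id <- paste(events$participant, events$block, events$trial)
  trials <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    j <- match(ev_id[i], key_id)
    if (is.na(j)) {
      warning(
        sprintf(
          "No samples for participant %s block %d trial %d; trial skipped.",
          ev$participant, ev$block, ev$trial
        ),
        call. = FALSE
      )
      next
    }
    s <- sample_groups[[j]]
    tr <- tryCatch(
      reach_trial(
        participant = ev$participant, group = ev$group,
        block = ev$block, trial = ev$trial,
        condition = as.character(ev$condition_ms), direction = ev$direction,
        target_onset_s = ev$target_onset_s, reach_onset_s = ev$reach_onset_s,
        touch_s = ev$touch_s, perturbation_s = ev$perturbation_s,
        touch_x_cm = ev$touch_x_cm, touch_y_cm = ev$touch_y_cm,
        samples = s[c("t_s", "x_cm", "y_cm", "z_cm")],
        sampling_rate_hz = fs
      ),
      error = function(e) {
        warning(
          sprintf(
            "Rejecting participant %s block %d trial %d: %s",
            ev$participant, ev$block, ev$trial, conditionMessage(e)
          ),
          call. = FALSE
        )
        NULL
      }
    )
    if (!is.null(tr)) trials[[length(trials) + 1L]] <- tr
  }
  reach_session(trials, sampling_rate_hz = fs)
}

#' Write or read a generator ground-truth table
#'
#' Thin CSV wrappers so simulated sessions can carry their validation labels
#' (injected correction onsets, artifact and outlier flags) alongside the
#' data files.
#'
#' @param ground_truth Tibble as produced by [generate_session()].
#' @param path CSV file path.
#' @return `write_ground_truth()` returns the path invisibly;
#'   `read_ground_truth()` returns the tibble.
#' @export
write_ground_truth <- function(ground_truth, path) {
  readr::write_csv(ground_truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
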