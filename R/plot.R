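#' Diagnostic plot of an envelope and a perturbed trial
#'
#' Plots the non-perturbed mean horizontal trace with its +/- k SD band and
#' overlays one perturbed trial, marking the detected correction onset —
#' the visual check behind every envelope-based latency estimate. Requires
#' ggplot2.
#'
#' @param envelope A [build_envelope()] result.
#' @param trial Optional perturbed [reach_trial()] to overlay.
#' @param detection Optional one-row result of [detect_correction()] for the
#'   trial, used to mark the onset.
#' @return A ggplot object.
#' @export
plot_envelope <- function(envelope, trial = NULL, detection = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_envelope() requires ggplot2.", call. = FALSE)
  }
  b <- envelope$bands
  g <- ggplot2::ggplot(b, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_x_cm - envelope$k * .data$sd_x_cm,
        ymax = .data$mean_x_cm + envelope$k * .data$sd_x_cm
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_x_cm)) +
    ggplot2::labs(
      x = "Time from reach onset (ms)", y = "Horizontal position (cm)",
      title = sprintf("Envelope %s (+/- %g SD)", envelope$grouping, envelope$k)
    )
  if (!is.null(trial)) {
    s <- movement_samples(trial)
    td <- tibble::tibble(
      time_ms = (s$t_s - trial$reach_onset_s) * 1000,
      x_cm = s$x_cm
    )
    g <- g + ggplot2::geom_line(
      data = td, ggplot2::aes(y = .data$x_cm),
      colour = "red", linetype = "dashed"
    )
    if (!is.null(detection) && isTRUE(detection$detected)) {
      t_on <- (trial$perturbation_s - trial$reach_onset_s) * 1000 +
        detection$correction_latency_ms
      g <- g + ggplot2::geom_vline(xintercept = t_on, colour = "red")
    }
  }
  g
}
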