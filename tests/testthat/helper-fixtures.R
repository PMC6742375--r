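# Shared fixture configurations and independent brute-force oracles.

# Fully deterministic generator: no positional noise, no motor scatter, no
# timing variability, no contaminants. Trials are exact template reaches.
noiseless_config <- function(correction_prob = 0, peak_frac = 0.5, ...) {
  gp <- function(lat, dur) {
    group_params(
      reach_latency_mean_ms = lat, reach_latency_sd_ms = 0,
      reach_duration_mean_ms = dur, reach_duration_sd_ms = 0,
      peak_frac = peak_frac,
      correction_latency_sd_ms = 0,
      correction_prob = c(
        "0_left" = correction_prob, "0_right" = correction_prob,
        "200_left" = correction_prob, "200_right" = correction_prob
      ),
      participant_latency_sd_ms = 0, participant_duration_sd_ms = 0,
      artifact_rate = 0, outlier_rate = 0
    )
  }
  generator_config(
    groups = list(younger = gp(266, 496), older = gp(294, 532)),
    endpoint_sd_cm = 0, wobble_sd_cm = 0, noise_sd_cm = 0,
    ...
  )
}

# Low-variability configuration for detector-validation runs: small motor
# scatter and sensor noise, every correction injected.
low_noise_config <- function() {
  gp <- group_params(
    reach_latency_mean_ms = 266, reach_duration_mean_ms = 496,
    correction_prob = c(
      "0_left" = 1, "0_right" = 1, "200_left" = 1, "200_right" = 1
    ),
    participant_latency_sd_ms = 0, participant_duration_sd_ms = 0,
    artifact_rate = 0, outlier_rate = 0
  )
  generator_config(
    groups = list(younger = gp),
    endpoint_sd_cm = 0.01, wobble_sd_cm = 0.01, noise_sd_cm = 0.005
  )
}

clean_overrides <- function(...) {
  utils::modifyList(list(artifact = NA_character_, outlier = FALSE), list(...))
}

# Generate n filtered static trials for envelope support.
make_envelope_trials <- function(config, n, group = "younger", filter = TRUE) {
  lapply(seq_len(n), function(i) {
    tr <- generate_trial(
      config, group,
      participant = "ENV", block = 1L, trial = i,
      overrides = clean_overrides()
    )$trial
    if (filter) filter_trial(tr) else tr
  })
}

# Independent oracle: exhaustive per-sample scan of the envelope rule.
# Deliberately loop-based and structured differently from detect_correction().
oracle_detect_latency <- function(trial, env, min_delay_ms = 80, sustain = 3) {
  fs <- trial$sampling_rate_hz
  s <- movement_samples(trial)
  s <- s[round((s$t_s - trial$reach_onset_s) * fs) >= 0, , drop = FALSE]
  side <- if (trial$direction == "right") 1 else -1
  nb <- nrow(env$bands)
  outside <- logical(nrow(s))
  for (i in seq_len(nrow(s))) {
    j <- round((s$t_s[i] - trial$reach_onset_s) * fs)
    jj <- min(max(j, 0), nb - 1) + 1
    outside[i] <- side * (s$x_cm[i] - env$bands$mean_x_cm[jj]) >
      env$k * env$bands$sd_x_cm[jj]
  }
  tp <- trial$perturbation_s
  eps <- 0.5 / fs
  idx <- which(s$t_s >= tp - eps)
  i <- 1
  while (i <= length(idx)) {
    if (!outside[idx[i]]) {
      i <- i + 1
      next
    }
    j2 <- i
    while (j2 < length(idx) && outside[idx[j2 + 1]]) j2 <- j2 + 1
    run_len <- j2 - i + 1
    if (run_len >= sustain &&
      s$t_s[idx[j2]] >= tp + min_delay_ms / 1000 - eps) {
      return(max(min_delay_ms, (s$t_s[idx[i]] - tp) * 1000))
    }
    i <- j2 + 1
  }
  NA_real_
}

# Independent oracle: per-sample perpendicular distance to the start-end line
# via the cross-product formula (vs the projection method in the package).
oracle_mpo <- function(samples) {
  p <- as.matrix(samples[c("x_cm", "y_cm", "z_cm")])
  s0 <- p[1, ]
  e <- p[nrow(p), ]
  w <- e - s0
  B <- sqrt(sum(w^2))
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(nrow(p))) {
    v <- p[i, ] - s0
    cr <- c(
      v[2] * w[3] - v[3] * w[2],
      v[3] * w[1] - v[1] * w[3],
      v[1] * w[2] - v[2] * w[1]
    )
    d <- sqrt(sum(cr^2)) / B
    if (d > best + 1e-12) {
      best <- d
      best_i <- i
    }
  }
  list(A = best, B = B, L = best / B, argmax = best_i)
}

# First sample at which a trace departs from a template x-trace.
oracle_template_departure <- function(trial, template, tol = 1e-9) {
  n <- min(nrow(trial$samples), nrow(template$samples))
  dx <- abs(trial$samples$x_cm[1:n] - template$samples$x_cm[1:n])
  i <- which(dx > tol)
  if (!length(i)) {
    return(NA_real_)
  }
  trial$samples$t_s[i[1]]
}
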