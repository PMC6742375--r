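test_that("MAD rule flags the textbook cases", {
  expect_identical(mad_outliers(c(2, 3, 4, 100)), c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(mad_outliers(c(5, 5, 5, 5)), rep(FALSE, 4))
  expect_identical(mad_outliers(c(1, 2, 3, 4, 5)), rep(FALSE, 5))
  # MAD = 0: anything off the median is flagged
  expect_identical(mad_outliers(c(1, 1, 1, 1, 2)), c(rep(FALSE, 4), TRUE))
})

test_that("MAD rule warns and flags nothing below 4 values", {
  expect_warning(out <- mad_outliers(c(1, 2, 100)), "Fewer than 4")
  expect_identical(out, rep(FALSE, 3))
})

test_that("MAD mask is shift-invariant and scale-equivariant", {
  set.seed(8)
  for (i in 1:20) {
    v <- c(stats::rnorm(30), stats::rnorm(2, 0, 15))
    m <- mad_outliers(v)
    expect_identical(mad_outliers(v + 1234.5), m)
    expect_identical(mad_outliers(v * 6.75), m)
  }
})

test_that("error screening removes each artifact type with the right reason", {
  cfg <- noiseless_config()
  mk <- function(art, trial) {
    generate_trial(cfg, "younger",
      trial = trial,
      overrides = clean_overrides(artifact = art)
    )$trial
  }
  trials <- list(
    mk(NA_character_, 1L),
    mk("missing_touch", 2L),
    mk("premature_start", 3L),
    mk("sample_gap", 4L),
    mk("empty_trajectory", 5L)
  )
  scr <- screen_error_trials(reach_session(trials, cfg$sampling_rate_hz))
  expect_equal(length(scr$session), 1)
  expect_equal(scr$session$trials[[1]]$trial, 1L)
  expect_identical(
    scr$removals$reason[order(scr$removals$trial)],
    c("missing_touch", "premature_start", "sample_gap", "zero_length")
  )
  expect_equal(sum(scr$report$n_removed) + sum(scr$report$n_retained), 5)
})

test_that("clean sessions pass screening untouched", {
  cfg <- noiseless_config()
  out <- generate_session(
    generator_config(
      groups = cfg$groups, trials_per_block = 20, blocks = 1,
      endpoint_sd_cm = 0, wobble_sd_cm = 0, noise_sd_cm = 0
    ),
    "P01", "younger",
    seed = 12
  )
  scr <- screen_error_trials(out$session)
  expect_equal(length(scr$session), 20)
  expect_equal(nrow(scr$removals), 0)
})

test_that("cleaning recovers injected contaminants without false removals", {
  # deterministic clean trials + 5%/5% injected artifact and outlier trials
  gp <- function(lat, dur) {
    group_params(
      reach_latency_mean_ms = lat, reach_latency_sd_ms = 0,
      reach_duration_mean_ms = dur, reach_duration_sd_ms = 0,
      correction_prob = c(
        "0_left" = 0, "0_right" = 0, "200_left" = 0, "200_right" = 0
      ),
      participant_latency_sd_ms = 0, participant_duration_sd_ms = 0,
      artifact_rate = 0.05, outlier_rate = 0.05
    )
  }
  cfg <- generator_config(
    groups = list(younger = gp(266, 496)),
    endpoint_sd_cm = 0, wobble_sd_cm = 0, noise_sd_cm = 0,
    trials_per_block = 80, blocks = 2
  )
  out <- generate_session(cfg, "P01", "younger", seed = 31)
  gt <- out$ground_truth
  scr <- screen_error_trials(out$session)
  filt <- filter_session(scr$session)
  dv <- kinematics_table(filt)
  mad <- screen_outlier_trials(dv)
  removed <- c(scr$removals$trial, mad$removals$trial)
  contaminated <- gt$trial[!is.na(gt$artifact) | gt$outlier]
  clean <- setdiff(gt$trial, contaminated)
  expect_gte(sum(contaminated %in% removed) / length(contaminated), 0.95)
  expect_equal(sum(clean %in% removed), 0)
})

test_that("cleaning report balances removed and retained counts", {
  info <- tibble::tibble(
    participant = rep(c("A", "B"), each = 4),
    condition = rep(c("none", "0"), 4),
    direction = rep(c("none", "left"), 4)
  )
  keep <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  rep_tab <- cleaning_report(info, keep, stage = "test")
  expect_true(all(rep_tab$n_removed + rep_tab$n_retained == rep_tab$n_input))
  expect_equal(sum(rep_tab$n_removed), sum(!keep))
})
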