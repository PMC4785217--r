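test_that("resampling decimates cleanly and preserves slow signals", {
  x <- eda_trace(rep(2.5, 10000), 1000)
  r <- resample_trace(x, 100)
  expect_equal(length(r$values), 1000L)
  expect_equal(r$sampling_rate, 100)
  expect_equal(r$values, rep(2.5, 1000), tolerance = 1e-9)

  tt <- seq(1e-3, 30, by = 1e-3)
  s <- eda_trace(2 + sin(2 * pi * 0.1 * tt), 1000)
  rs <- resample_trace(s, 100)
  expect_equal((max(rs$values) - min(rs$values)) / 2, 1, tolerance = 0.01)

  expect_error(resample_trace(eda_trace(1:100, 250), 100), "integer multiple")
  expect_identical(resample_trace(x, 1000), x)
})

test_that("log transform obeys log laws and the floor", {
  expect_equal(log_transform(1.0), 0)
  expect_equal(log_transform(10.0), 1)
  expect_equal(log_transform(0), log10(1e-3))
  v <- runif(100, 0.5, 20)
  expect_equal(log_transform(3.7 * v), log_transform(v) + log10(3.7))
  tr <- log_transform(eda_trace(v, 100))
  expect_s3_class(tr, "eda_trace")
  expect_equal(tr$unit, "log10uS")
})

test_that("baseline is the mean over the final ITI window", {
  v <- rep(0.4, 1000)                       # 10 s at 100 Hz
  tr <- structure(list(values = v, sampling_rate = 100, t0 = 0,
                       unit = "log10uS"), class = "eda_trace")
  expect_equal(baseline_value(tr, 10, 2), 0.4)

  # step from a to b at the window midpoint -> (a + b) / 2
  v2 <- c(rep(0.1, 900), rep(0.5, 100))     # step at t = 9 s
  tr2 <- structure(list(values = v2, sampling_rate = 100, t0 = 0,
                        unit = "log10uS"), class = "eda_trace")
  expect_equal(baseline_value(tr2, 10, 2), 0.3)

  expect_error(baseline_value(tr, 1, 2), "outside")
  expect_error(baseline_value(tr, 11, 2), "outside")
})

test_that("phase summary takes the signed max change over bins 2-4", {
  pcfg <- preprocess_config()
  flat <- structure(list(values = rep(0.2, 2000), sampling_rate = 100,
                         t0 = 0, unit = "log10uS"), class = "eda_trace")
  expect_equal(phase_summary(flat, 5, 0.2, pcfg), 0)

  bump_in_bin <- function(k, d) {
    v <- rep(0.2, 2000)
    idx <- (5 + (k - 1) * 2) * 100 + seq_len(200)   # bin k of onset 5 s
    v[idx] <- v[idx] + d
    structure(list(values = v, sampling_rate = 100, t0 = 0,
                   unit = "log10uS"), class = "eda_trace")
  }
  expect_equal(phase_summary(bump_in_bin(3, 0.07), 5, 0.2, pcfg), 0.07)
  # elevation confined to bin 1 is invisible to the bins 2-4 summary
  expect_equal(phase_summary(bump_in_bin(1, 0.5), 5, 0.2, pcfg), 0)
  # a sustained dip across bins 2-4 yields a negative (signed) summary
  v <- rep(0.2, 2000)
  v[(5 + 2) * 100 + seq_len(600)] <- 0.2 - 0.05
  dip <- structure(list(values = v, sampling_rate = 100, t0 = 0,
                        unit = "log10uS"), class = "eda_trace")
  expect_equal(phase_summary(dip, 5, 0.2, pcfg), -0.05)
  # truncated coverage is flagged missing
  expect_true(is.na(phase_summary(flat, 14, 0.2, pcfg)))
})

test_that("phase summary matches a brute-force oracle on random trials", {
  pcfg <- preprocess_config()
  set.seed(101)
  for (i in 1:200) {
    n <- 1600
    v <- cumsum(rnorm(n, 0, 0.01)) + runif(1, -1, 1)
    tr <- structure(list(values = v, sampling_rate = 100, t0 = 0,
                         unit = "log10uS"), class = "eda_trace")
    onset <- runif(1, 0, 7.9)
    base <- runif(1, -1, 1)
    # oracle: explicit loop over bins and samples
    means <- numeric(4)
    for (k in 1:4) {
      lo <- onset + (k - 1) * 2; hi <- onset + k * 2
      sel <- which((seq_len(n) - 1) / 100 >= lo - 1e-9 &
                     (seq_len(n) - 1) / 100 < hi - 1e-9)
      means[k] <- mean(v[sel])
    }
    expect_identical(phase_summary(tr, onset, base, pcfg),
                     max(means[2:4] - base))
  }
})

test_that("summaries are invariant to multiplicative trace rescaling", {
  cfg <- schedule_config(n_win = 2L, n_loss = 2L, n_near_win = 1L,
                         n_near_loss = 1L, n_filler = 1L, rest_duration = 20)
  rcc <- run_config(schedule = cfg, n_participants = 2, master_seed = 5)
  sim <- simulate_cohort(rcc, keep_raw = TRUE)
  s1 <- sim$sessions[[1]]
  for (c_mult in c(0.25, 3, 40)) {
    scaled <- eda_trace(c_mult * s1$trace$values, s1$trace$sampling_rate)
    r0 <- trial_records(s1$trace, s1$schedule, s1$timeline, "a")
    r1 <- trial_records(scaled, s1$schedule, s1$timeline, "a")
    expect_equal(r1$selection_eda, r0$selection_eda, tolerance = 1e-9)
    expect_equal(r1$outcome_eda, r0$outcome_eda, tolerance = 1e-9)
  }
})

test_that("nonresponder screening excludes flat traces only", {
  rec <- data.frame(participant_id = rep(c("a", "b"), each = 10),
                    outcome_eda = c(rnorm(10, 0, 0.05), rep(0.02, 10)))
  scr <- screen_nonresponders(rec)
  expect_equal(scr$included, "a")
  expect_equal(scr$excluded, "b")

  scr0 <- screen_nonresponders(rec, preprocess_config(nonresponder_min_sd = 0))
  expect_equal(length(scr0$excluded), 0L)

  flat <- data.frame(participant_id = rep("a", 5), outcome_eda = rep(1, 5))
  expect_error(screen_nonresponders(flat), "nonresponders")
})

test_that("trial table has one record per trial with task magnitudes", {
  cfg <- schedule_config()
  rcc <- run_config(schedule = cfg, n_participants = 2, master_seed = 8)
  sim <- simulate_cohort(rcc, keep_raw = TRUE)
  rec <- sim$records
  expect_equal(nrow(rec), 2 * 76)
  expect_equal(sum(rec$included), 2 * 58)    # fillers flagged out
  expect_false(any(rec$missing))

  win <- rec[rec$condition == "win", ]
  expect_equal(win$magnitude, 10 * win$bet)
  expect_equal(win$outcome_pence, 10 * win$bet)
  nl <- rec[rec$condition == "near_loss", ]
  expect_true(all(nl$outcome_pence == 0))
  expect_equal(nl$magnitude, 10 * nl$bet)
  expect_equal(nl$magnitude_signed, -10 * nl$bet)
  expect_true(all(rec$magnitude >= 0))
})

test_that("a session round-trips through events.tsv and physio files", {
  cfg <- schedule_config(n_win = 2L, n_loss = 2L, n_near_win = 1L,
                         n_near_loss = 1L, n_filler = 1L, rest_duration = 20)
  rcc <- run_config(schedule = cfg, n_participants = 2, master_seed = 12)
  sim <- simulate_cohort(rcc, keep_raw = TRUE)
  s1 <- sim$sessions[[1]]
  ev <- withr::local_tempfile(fileext = ".tsv")
  ph <- withr::local_tempfile(fileext = ".tsv.gz")
  bh <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(s1$schedule, s1$timeline, ev)
  write_physio(s1$trace, ph, participant_id = "p01")
  write_behavior_tsv(s1$schedule, bh)
  rec <- preprocess_session(ev, ph, bh)
  direct <- trial_records(s1$trace, s1$schedule, s1$timeline, "p01")
  expect_equal(rec$outcome_eda, direct$outcome_eda, tolerance = 1e-4)
  expect_equal(rec$condition, direct$condition)
  expect_equal(rec$luck_rating, s1$schedule$luck_rating)
})
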