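test_that("SCR kernel is unit-peak, zero at onset, with the closed-form peak", {
  expect_equal(scr_kernel(0), 0)
  expect_equal(scr_kernel(-1), 0)
  tt <- seq(0, 30, by = 1e-4)
  h <- scr_kernel(tt)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(h)], scr_peak_time(0.75, 4), tolerance = 1e-3)
  expect_equal(scr_peak_time(0.75, 4), 1.5452090156, tolerance = 1e-9)
  expect_error(scr_kernel(1, rise = 4, decay = 0.75), "rise")
  expect_error(amplitude_model(scr_rise = 5, scr_decay = 4), "scr_rise")
})

test_that("a single event produces a deflection equal to its amplitude", {
  cfg <- schedule_config(n_win = 1L, n_loss = 0L, n_near_win = 0L,
                         n_near_loss = 0L, n_filler = 0L,
                         rest_duration = 60)
  # choice events silenced so the outcome response stands alone
  amp <- amp_noise_free(selection_slope = 0, selection_intercept = 0)
  s <- generate_schedule(cfg, seed = 1)
  s <- simulate_bets(s, policy_deterministic(), cfg)
  tl <- build_event_timeline(s, cfg, seed = 2)
  tr <- synthesize_trace(tl, s, amp, seed = 3)
  lt <- log_transform(tr)
  a_out <- tr$amplitudes$outcome[1]
  expect_gt(a_out, 0)
  # peak deflection in the outcome window equals amplitude x kernel max (= 1)
  w <- which((seq_along(lt$values) - 1) / lt$sampling_rate >=
               tl$outcome_onset[1])
  expect_equal(max(lt$values[w]) - amp$tonic_log10, a_out, tolerance = 1e-4)

  # and the binned max-change summary equals amplitude x closed-form kappa
  pcfg <- preprocess_config()
  base <- baseline_value(lt, tl$choice_onset[1], 2)
  ps <- phase_summary(lt, tl$outcome_onset[1], base, pcfg)
  kappa <- kernel_bin_attenuation(amp, pcfg)
  expect_equal(ps, a_out * kappa, tolerance = 2e-3)
})

test_that("silent generative model yields a constant trace", {
  cfg <- schedule_config(n_win = 2L, n_loss = 2L, n_near_win = 0L,
                         n_near_loss = 0L, n_filler = 0L, rest_duration = 10)
  amp <- amp_noise_free(selection_slope = 0, win_slope = 0, loss_slope = 0,
                        near_win_slope = 0, near_loss_slope = 0,
                        selection_intercept = 0, outcome_intercept = 0)
  s <- simulate_bets(generate_schedule(cfg, seed = 4),
                     policy_deterministic(), cfg)
  tl <- build_event_timeline(s, cfg, seed = 5)
  tr <- synthesize_trace(tl, s, amp, seed = 6)
  expect_equal(diff(range(tr$values)), 0)
  expect_equal(unique(tr$values), 10^amp$tonic_log10)
})

test_that("trace synthesis is seed-deterministic", {
  cfg <- schedule_config(n_win = 3L, n_loss = 3L, n_near_win = 2L,
                         n_near_loss = 2L, n_filler = 2L, rest_duration = 20)
  amp <- amplitude_model()
  s <- simulate_bets(generate_schedule(cfg, seed = 7), bet_policy(), cfg,
                     seed = 8)
  tl <- build_event_timeline(s, cfg, seed = 9)
  t1 <- synthesize_trace(tl, s, amp, seed = 10)
  t2 <- synthesize_trace(tl, s, amp, seed = 10)
  expect_identical(t1$values, t2$values)
  t3 <- synthesize_trace(tl, s, amp, seed = 11)
  expect_false(identical(t1$values, t3$values))
})

test_that("physio writer and reader round-trip trace and sidecar", {
  tr <- eda_trace(2 + sin(seq(0, 20, by = 0.01))[-1], 100, t0 = 0)
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  write_physio(tr, f, participant_id = "p07", seed = 123)
  back <- read_physio(f)
  expect_equal(back$sampling_rate, 100)
  expect_equal(back$values, tr$values, tolerance = 1e-6)
  expect_equal(attr(back, "participant_id"), "p07")
  expect_true(file.exists(sub("\\.tsv\\.gz$", ".json", f)))
})
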