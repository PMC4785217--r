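test_that("generated schedules conserve the configured condition counts", {
  cfg <- schedule_config()
  s <- generate_schedule(cfg, seed = 1)
  expect_equal(nrow(s), 76L)
  counts <- table(s$condition)
  expect_equal(unname(counts[c("win", "loss", "near_win", "near_loss",
                               "filler")]),
               c(19L, 19L, 10L, 10L, 18L), ignore_attr = TRUE)

  cfg2 <- schedule_config(n_win = 3L, n_loss = 5L, n_near_win = 0L,
                          n_near_loss = 2L, n_filler = 1L)
  s2 <- generate_schedule(cfg2, seed = 2)
  expect_equal(sum(s2$condition == "win"), 3L)
  expect_equal(sum(s2$condition == "near_win"), 0L)
  expect_equal(nrow(s2), 11L)
})

test_that("degenerate and invalid configurations are handled", {
  cfg1 <- schedule_config(n_win = 1L, n_loss = 0L, n_near_win = 0L,
                          n_near_loss = 0L, n_filler = 0L)
  s <- generate_schedule(cfg1, seed = 1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$condition, "win")

  cfg0 <- schedule_config(n_win = 0L, n_loss = 0L, n_near_win = 0L,
                          n_near_loss = 0L, n_filler = 0L)
  expect_error(generate_schedule(cfg0, seed = 1), "positive")
  expect_error(schedule_config(n_win = -1L), "non-negative")
  expect_error(schedule_config(bet_levels = c(10, 10, 20)), "increasing")
  expect_error(schedule_config(anticipation_range = c(6.9, 5.3)),
               "interval")
  expect_error(schedule_config(payoff_multiplier = 0), "payoff")
})

test_that("schedule generation is seed-deterministic", {
  cfg <- schedule_config()
  a <- generate_schedule(cfg, seed = 42)
  b <- generate_schedule(cfg, seed = 42)
  expect_identical(a, b)
  c <- generate_schedule(cfg, seed = 43)
  expect_false(identical(a$condition, c$condition))
})

test_that("outcome geometry respects segment structure", {
  cfg <- schedule_config(n_win = 0L, n_loss = 0L, n_near_win = 5000L,
                         n_near_loss = 5000L, n_filler = 0L)
  s <- generate_schedule(cfg, seed = 3)
  expect_true(all(s$angular_offset > 0))
  expect_true(all(s$angular_offset <= 1.8))

  cfg2 <- schedule_config()
  s2 <- generate_schedule(cfg2, seed = 4)
  fill <- s2[s2$condition == "filler", ]
  expect_true(all(fill$angular_offset >= cfg2$filler_center_margin))
  expect_true(all(fill$angular_offset > cfg2$near_offset_max))
  hit <- s2[s2$condition %in% c("win", "loss"), ]
  expect_true(all(hit$angular_offset > cfg2$near_offset_max))
  expect_true(all(hit$angular_offset <= cfg2$segment_half_width))
})

test_that("payoffs, counterfactuals and sounds follow the task rules", {
  cfg <- schedule_config()
  s <- generate_schedule(cfg, seed = 5)
  s <- simulate_bets(s, bet_policy(), cfg, seed = 6)
  win <- s$condition == "win"; loss <- s$condition == "loss"
  near <- s$condition %in% c("near_win", "near_loss")
  expect_equal(s$obtained_outcome[win], 10 * s$bet[win])
  expect_equal(s$obtained_outcome[loss], -10 * s$bet[loss])
  expect_true(all(s$obtained_outcome[!(win | loss)] == 0))
  expect_equal(s$counterfactual_magnitude[near], 10 * s$bet[near])
  expect_true(all(s$counterfactual_magnitude[!near] == 0))
  expect_equal(unique(s$feedback_sound[win]), "applause")
  expect_equal(unique(s$feedback_sound[loss]), "boo")
  expect_equal(unique(s$feedback_sound[!(win | loss)]), "thud")
})

test_that("event timelines are monotone with the configured phase timing", {
  cfg <- schedule_config()
  s <- generate_schedule(cfg, seed = 7)
  tl <- build_event_timeline(s, cfg, seed = 8)
  antic <- tl$outcome_onset - tl$spin_onset
  expect_true(all(antic >= 5.3 & antic <= 6.9))
  expect_equal(tl$iti_end - tl$iti_start, rep(10, nrow(tl)))
  expect_equal(tl$choice_onset[-1], tl$iti_end[-nrow(tl)])
  ev <- as.matrix(tl[, c("choice_onset", "spin_onset", "outcome_onset",
                         "rating_onset", "iti_start", "iti_end")])
  # strictly increasing within each trial; consecutive trials abut exactly
  expect_true(all(apply(ev, 1, function(r) all(diff(r) > 0))))
  expect_true(all(diff(as.vector(t(ev))) >= 0))
  expect_equal(tl$choice_onset[1], cfg$rest_duration)
})

test_that("latency draws are floored at the configured minimum", {
  cfg <- schedule_config()
  s <- generate_schedule(cfg, seed = 9)
  zero_model <- list(choice = function(n) numeric(n),
                     rating = function(n) numeric(n))
  tl <- build_event_timeline(s, cfg, seed = 10, latency_model = zero_model)
  expect_equal(tl$spin_onset - tl$choice_onset, rep(0.2, nrow(tl)))
  expect_equal(tl$iti_start - tl$rating_onset, rep(0.2, nrow(tl)))
})

test_that("events.tsv is byte-identical under a fixed seed and round-trips", {
  cfg <- schedule_config()
  make <- function(path) {
    s <- generate_schedule(cfg, seed = 11)
    s <- simulate_bets(s, bet_policy(), cfg, seed = 12)
    tl <- build_event_timeline(s, cfg, seed = 13)
    write_events_tsv(s, tl, path)
    list(s = s, tl = tl)
  }
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  x1 <- make(f1); x2 <- make(f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_events_tsv(f1)
  expect_equal(back$schedule$condition, x1$s$condition)
  expect_equal(back$schedule$bet, x1$s$bet)
  expect_equal(back$schedule$obtained_outcome, x1$s$obtained_outcome)
  expect_equal(back$timeline$outcome_onset, x1$tl$outcome_onset,
               tolerance = 1e-5)
  expect_equal(back$timeline$iti_end, x1$tl$iti_end, tolerance = 1e-5)
})
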