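test_that("slope estimator is exact on noise-free data", {
  mags <- rep(c(100, 300, 500, 700, 900), 4)
  # no participant effects: pooled fallback recovers the slope exactly
  rec <- make_linear_records(8.35e-5, rep(0.02, 6), mags)
  f <- quiet(fit_magnitude_slope(rec, "outcome_eda", "magnitude", "loss"))
  expect_equal(f$b, 8.35e-5, tolerance = 1e-7)

  # participant intercepts on a balanced design: REML slope equals the
  # within-participant (demeaned) OLS slope
  ints <- seq(0.01, 0.06, length.out = 6)
  rec2 <- make_linear_records(8.35e-5, ints, mags)
  set.seed(5)
  rec2$outcome_eda <- rec2$outcome_eda + rnorm(nrow(rec2), 0, 1e-3)
  f2 <- quiet(fit_magnitude_slope(rec2, "outcome_eda", "magnitude", "loss"))
  g <- factor(rec2$participant_id)
  xw <- rec2$magnitude - ave(rec2$magnitude, g)
  yw <- rec2$outcome_eda - ave(rec2$outcome_eda, g)
  expect_lt(abs(f2$b - sum(xw * yw) / sum(xw * xw)), 1e-6)
  expect_equal(abs(f2$t), abs(f2$b) / f2$se, tolerance = 1e-6)
})

test_that("per-participant slopes agree with lm and flag degenerate input", {
  set.seed(11)
  rec <- make_linear_records(5e-5, c(0.01, 0.03, 0.05), rep(c(100, 500, 900), 5))
  rec$outcome_eda <- rec$outcome_eda + rnorm(nrow(rec), 0, 0.01)
  sl <- per_participant_slopes(rec, "outcome_eda", "magnitude")
  for (id in unique(rec$participant_id)) {
    d <- rec[rec$participant_id == id, ]
    expect_equal(unname(sl[id]),
                 unname(coef(lm(outcome_eda ~ magnitude, d))[2]),
                 tolerance = 1e-8)
  }
  one_mag <- make_linear_records(5e-5, 0.02, rep(500, 6))
  expect_true(is.na(per_participant_slopes(one_mag, "outcome_eda",
                                           "magnitude")[1]))
})

test_that("paired slope test handles equal, degenerate and shifted inputs", {
  a <- setNames(rnorm(10), paste0("p", 1:10))
  t0 <- paired_slope_test(a, a)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_equal(t0$df, 9L)

  b <- a - 1   # constant difference of 1: zero variance
  td <- paired_slope_test(a, b)
  expect_true(td$degenerate)
  expect_lte(td$p, .Machine$double.xmin)
  expect_equal(td$estimate, 1)

  expect_error(paired_slope_test(a, setNames(rnorm(10), paste0("q", 1:10))),
               "participant")
  expect_error(paired_slope_test(a[1:2], a[1:2]), "3")
})

test_that("one-sample t matches hand computation", {
  r <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$df, 2L)
  expect_equal(one_sample_t(c(-2, -1, 1, 2), 0)$statistic, 0)
  expect_equal(one_sample_t(rnorm(20))$df, 19L)
  expect_true(one_sample_t(rep(4, 5), 4)$degenerate)
})

test_that("Williams test matches its closed form and symmetry properties", {
  # equal correlations -> t exactly 0, regardless of r23
  for (r23 in c(-0.3, 0, 0.6)) {
    w <- williams_test(0.41, 0.41, r23, 30)
    expect_equal(w$statistic, 0)
    expect_equal(w$p, 1)
  }
  # df = n - 3
  expect_equal(williams_test(0.5, 0.3, 0.2, 50)$df, 47)
  # frozen independent evaluation of the Steiger-Williams formula
  w <- williams_test(0.76, 0.55, 0.50, 50)
  expect_equal(w$statistic, 2.2263695294, tolerance = 1e-9)
  expect_equal(w$p, 0.0308203693, tolerance = 1e-8)
  # antisymmetry under swapping the two dependent correlations
  w2 <- williams_test(0.55, 0.76, 0.50, 50)
  expect_equal(w2$statistic, -w$statistic, tolerance = 1e-12)
  # domain errors
  expect_error(williams_test(0.9, -0.9, 0.9, 50), "positive semidefinite")
  expect_error(williams_test(0.5, 0.3, 0.2, 3), "n >= 4")
  expect_error(williams_test(1, 0.3, 0.2, 50), "within")
})

test_that("slope-profile correlations behave at the extremes", {
  a <- setNames(rnorm(30), paste0("p", 1:30))
  expect_equal(correlate_slope_profiles(a, a)$r, 1)
  const <- setNames(rep(2, 30), names(a))
  expect_true(correlate_slope_profiles(a, const)$constant)
  set.seed(77)
  n <- 400
  x <- setNames(rnorm(n), paste0("p", 1:n))
  y <- setNames(rnorm(n), paste0("p", 1:n))
  expect_lt(abs(correlate_slope_profiles(x, y)$r), 3 / sqrt(n))
  expect_error(correlate_slope_profiles(a[1:3], a[1:3]), "4")
})

test_that("behaviour summary computes change scores in session order", {
  rec <- data.frame(participant_id = "a", trial_index = 1:4,
                    condition = c("win", "loss", "filler", "win"),
                    bet = c(50, 40, 50, 50),
                    outcome_pence = c(500, -400, 0, 500))
  bs <- behavior_summary(rec)
  p <- bs$participants
  expect_equal(p$post_win_change, -10)   # only trial 1 is followed by a bet
  expect_equal(p$post_loss_change, 10)
  expect_equal(p$total_winnings_gbp, 6)
  expect_equal(p$mean_bet, 47.5)

  flat <- data.frame(participant_id = rep(c("a", "b"), each = 3),
                     trial_index = rep(1:3, 2),
                     condition = rep(c("win", "loss", "near_win"), 2),
                     bet = 50, outcome_pence = rep(c(500, -500, 0), 2))
  bf <- behavior_summary(flat)
  expect_equal(bf$post_win_change, 0)
  expect_equal(bf$post_loss_change, 0)
  expect_equal(bf$total_winnings_gbp, 0)

  nulls <- data.frame(participant_id = "a", trial_index = 1:3,
                      condition = "near_win", bet = 50, outcome_pence = 0)
  expect_equal(behavior_summary(nulls)$total_winnings_gbp, 0)
})
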