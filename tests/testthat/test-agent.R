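test_that("anchored agent with zero shift and noise always bets the anchor", {
  cfg <- schedule_config()
  s <- generate_schedule(cfg, seed = 1)
  pol <- bet_policy(post_win_shift = 0, post_loss_shift = 0, shift_sd = 0)
  s <- simulate_bets(s, pol, cfg)
  expect_true(all(s$bet == 50))
})

test_that("deterministic post-win update lands on the 40 p grid point", {
  cfg <- schedule_config()
  s <- make_schedule(c("win", "filler"), c(50, 50), cfg)
  s <- simulate_bets(s, policy_deterministic(), cfg)
  # 50 - 5.77 = 44.23 -> nearest grid level is 40
  expect_equal(s$bet, c(50, 40))

  s2 <- make_schedule(c("loss", "filler"), c(50, 50), cfg)
  s2 <- simulate_bets(s2, policy_deterministic(), cfg)
  # 50 + 3.40 = 53.40 -> nearest grid level is 50
  expect_equal(s2$bet, c(50, 50))
})

test_that("bets stay on the grid and match an independent random-walk oracle", {
  cfg <- schedule_config(n_win = 2500L, n_loss = 2500L, n_near_win = 2500L,
                         n_near_loss = 2500L, n_filler = 0L)
  pol <- bet_policy()
  s <- generate_schedule(cfg, seed = 21)
  s <- simulate_bets(s, pol, cfg, seed = 22)
  expect_true(all(s$bet %in% pol$grid))

  # independent oracle: same walk re-implemented with plain arithmetic,
  # consuming the identical noise stream
  set.seed(22)
  noise <- rnorm(nrow(s), 0, pol$shift_sd)
  oracle <- numeric(nrow(s))
  oracle[1] <- 50
  for (t in seq_len(nrow(s) - 1L)) {
    shift <- switch(s$condition[t], win = -5.77, loss = 3.40, 0)
    x <- oracle[t] + shift + noise[t]
    g <- pol$grid
    d <- abs(g - x)
    oracle[t + 1L] <- g[which(d == min(d))[1]]   # ties take the lower level
  }
  expect_equal(s$bet, oracle)
  # mean bet of the walk sits in the interior of the grid
  expect_gt(mean(s$bet), 30)
  expect_lt(mean(s$bet), 60)
})

test_that("luck ratings follow the linear rule, rounding and clipping", {
  cfg <- schedule_config()
  s <- make_schedule(c("win", "loss", "near_win", "near_loss", "filler"),
                     rep(90, 5), cfg)
  flat <- luck_params(win_slope = 0, loss_slope = 0, near_win_slope = 0,
                      near_loss_slope = 0, rating_noise_sd = 0)
  expect_equal(simulate_luck_ratings(s, flat)$luck_rating, rep(5L, 5))

  lp <- luck_deterministic()
  r <- simulate_luck_ratings(s, lp)$luck_rating
  # win: 5 + 2.56e-3 * 900 = 7.304 -> 7
  expect_equal(r[1], 7L)
  # loss (signed magnitude -900): 5 + 2.29e-3 * (-900) = 2.939 -> 3
  expect_equal(r[2], 3L)
  # near-win: 5 - 1.34e-3 * 900 = 3.794 -> 4 (larger missed win: unluckier)
  expect_equal(r[3], 4L)
  # near-loss (signed -900): 5 - 1.21e-3 * (-900) = 6.089 -> 6 (luckier)
  expect_equal(r[4], 6L)
  expect_equal(r[5], 5L)

  # unsigned coding feeds positive magnitudes to every condition
  lpu <- luck_params(rating_noise_sd = 0, magnitude_coding = "unsigned")
  ru <- simulate_luck_ratings(s, lpu)$luck_rating
  expect_equal(ru[2], 7L)   # 5 + 2.29e-3 * 900 = 7.061
})

test_that("luck ratings are always within the 1-9 scale", {
  cfg <- schedule_config()
  s <- generate_schedule(cfg, seed = 31)
  s <- simulate_bets(s, bet_policy(), cfg, seed = 32)
  lp <- luck_params(rating_noise_sd = 25)
  r <- simulate_luck_ratings(s, lp, seed = 33)$luck_rating
  expect_true(all(r >= 1L & r <= 9L))
  expect_true(any(r == 1L) && any(r == 9L))  # clipping actually engaged
})
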