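#' Betting-agent policy
#'
#' A simple betting agent with asymmetric post-outcome adjustment: after a
#' win the next bet shifts by `post_win_shift`, after a loss by
#' `post_loss_shift`, and after any null outcome by zero; Gaussian noise of
#' SD `shift_sd` is added on every transition and the result is snapped to
#' the nearest bet-grid level (midpoints snap down) and clipped to the grid
#' range. Defaults reproduce the asymmetric gambler's-fallacy pattern: bets
#' drop by 5.77 p after wins and rise by 3.40 p after losses, with
#' transition noise of 9 p.
#'
#' @param anchor First bet in pence.
#' @param post_win_shift,post_loss_shift Signed bet adjustments (pence)
#'   applied after wins and losses.
#' @param shift_sd SD (pence) of the Gaussian noise on every bet transition.
#' @param grid Allowed bet levels in pence.
#' @return An object of class `bet_policy`.
#' @export
bet_policy <- function(anchor = 50, post_win_shift = -5.77,
                       post_loss_shift = 3.40, shift_sd = 9,
                       grid = seq(10, 90, by = 10)) {
  if (length(grid) < 1L) stop("bet grid must be non-empty", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("bet grid must be strictly increasing", call. = FALSE)
  if (shift_sd < 0) stop("shift_sd must be >= 0", call. = FALSE)
  structure(list(anchor = anchor, post_win_shift = post_win_shift,
                 post_loss_shift = post_loss_shift, shift_sd = shift_sd,
                 grid = as.numeric(grid)),
            class = "bet_policy")
}

#' Simulate bets for a schedule
#'
#' Runs the betting agent over the session in trial order, then refreshes
#' the monetary outcomes to match the simulated bets.
#'
#' @param schedule A schedule data frame (see [generate_schedule()]).
#' @param policy A [bet_policy()].
#' @param config The session's [schedule_config()] (for payoffs).
#' @param seed Optional integer seed.
#' @return The schedule with simulated `bet` and refreshed outcome columns.
#' @export
simulate_bets <- function(schedule, policy, config, seed = NULL) {
  stopifnot(inherits(policy, "bet_policy"))
  maybe_seed(seed)
  n <- nrow(schedule)
  cond <- schedule$condition
  shift <- ifelse(cond == "win", policy$post_win_shift,
           ifelse(cond == "loss", policy$post_loss_shift, 0))
  noise <- if (policy$shift_sd > 0) rnorm(n, 0, policy$shift_sd) else numeric(n)
  bet <- numeric(n)
  bet[1] <- snap_to_grid(policy$anchor, policy$grid)
  if (n > 1) {
    for (t in seq_len(n - 1L)) {
      bet[t + 1L] <- snap_to_grid(bet[t] + shift[t] + noise[t], policy$grid)
    }
  }
  schedule$bet <- bet
  finalize_outcomes(schedule, config)
}

# Vectorized bet walk for a cohort: `cond` is an n_trials x n_participants
# matrix of conditions; returns the matching matrix of bets. Same update
# rule as simulate_bets, with one noise draw per transition per participant.
simulate_bets_matrix <- function(cond, policy) {
  n <- nrow(cond); p <- ncol(cond)
  shift <- matrix(0, n, p)
  shift[cond == "win"] <- policy$post_win_shift
  shift[cond == "loss"] <- policy$post_loss_shift
  noise <- if (policy$shift_sd > 0) {
    matrix(rnorm(n * p, 0, policy$shift_sd), n, p)
  } else {
    matrix(0, n, p)
  }
  bet <- matrix(0, n, p)
  bet[1, ] <- snap_to_grid(rep(policy$anchor, p), policy$grid)
  if (n > 1) {
    for (t in seq_len(n - 1L)) {
      bet[t + 1L, ] <- snap_to_grid(bet[t, ] + shift[t, ] + noise[t, ],
                                    policy$grid)
    }
  }
  bet
}

#' Luck-rating generative parameters
#'
#' Trial-wise perceived-luck ratings on a 1-9 scale: rating =
#' `baseline_rating` + condition slope x outcome magnitude + noise, rounded
#' and clipped to the scale. By default magnitudes enter *signed* (losses
#' and near-losses negative), under which the default slopes reproduce the
#' qualitative pattern: larger wins feel luckier, larger losses unluckier,
#' larger missed wins unluckier, larger missed losses luckier. Set
#' `magnitude_coding = "unsigned"` to feed unsigned magnitudes instead (the
#' slopes are then interpreted per pence of unsigned magnitude and should be
#' re-signed by the caller).
#'
#' @param baseline_rating Scale midpoint used as the default rating.
#' @param win_slope,loss_slope,near_win_slope,near_loss_slope Rating units
#'   per pence of (signed) magnitude.
#' @param rating_noise_sd SD of Gaussian rating noise (rating units).
#' @param magnitude_coding `"signed"` (default) or `"unsigned"`.
#' @return An object of class `luck_params`.
#' @export
luck_params <- function(baseline_rating = 5,
                        win_slope = 2.56e-3, loss_slope = 2.29e-3,
                        near_win_slope = -1.34e-3, near_loss_slope = -1.21e-3,
                        rating_noise_sd = 1,
                        magnitude_coding = c("signed", "unsigned")) {
  if (rating_noise_sd < 0) stop("rating_noise_sd must be >= 0", call. = FALSE)
  structure(list(baseline_rating = baseline_rating,
                 win_slope = win_slope, loss_slope = loss_slope,
                 near_win_slope = near_win_slope,
                 near_loss_slope = near_loss_slope,
                 rating_noise_sd = rating_noise_sd,
                 magnitude_coding = match.arg(magnitude_coding)),
            class = "luck_params")
}

#' Simulate luck ratings for a schedule
#'
#' @param schedule A schedule with bets and outcomes assigned.
#' @param params A [luck_params()].
#' @param seed Optional integer seed.
#' @return The schedule with an integer `luck_rating` column in 1-9.
#' @export
simulate_luck_ratings <- function(schedule, params, seed = NULL) {
  stopifnot(inherits(params, "luck_params"))
  maybe_seed(seed)
  n <- nrow(schedule)
  mags <- trial_magnitudes(schedule)
  mag <- if (params$magnitude_coding == "signed") mags$signed else mags$unsigned
  slope <- luck_condition_slopes(params)[schedule$condition]
  noise <- if (params$rating_noise_sd > 0) {
    rnorm(n, 0, params$rating_noise_sd)
  } else {
    numeric(n)
  }
  raw <- params$baseline_rating + slope * mag + noise
  schedule$luck_rating <- as.integer(pmin(9, pmax(1, round(raw))))
  schedule
}

luck_condition_slopes <- function(params) {
  c(win = params$win_slope, loss = params$loss_slope,
    near_win = params$near_win_slope, near_loss = params$near_loss_slope,
    filler = 0)
}
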