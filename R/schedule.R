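#' Wheel-of-fortune session configuration
#'
#' Describes one session of the wheel-of-fortune gambling task: trial
#' condition counts, the bet grid, the payoff multiplier, near-miss geometry,
#' and phase timing. Defaults reproduce the task design: 76 trials (19 wins,
#' 19 losses, 10 near-wins, 10 near-losses, 18 fillers), bets on a 10-90
#' pence grid anchored at 50 p, +/-10x payoffs, near outcomes within 1.8
#' degrees of the segment boundary, a 5.3-6.9 s anticipation interval, a 1 s
#' outcome phase followed by a 1 s numeric display, and a 10 s intertrial
#' interval. The wheel is modelled as four 90-degree segments (gain, loss,
#' and two nulls), so offsets from the nearest boundary run from 0 to 45
#' degrees; filler stops land at least `filler_center_margin` degrees from
#' both boundaries of the null segment.
#'
#' @param n_win,n_loss,n_near_win,n_near_loss,n_filler Trial counts per
#'   condition.
#' @param payoff_multiplier Win/loss payoff as a multiple of the bet.
#' @param bet_levels Ordered bet grid in pence.
#' @param bet_anchor Starting bet in pence (must lie on the grid range).
#' @param near_offset_max Maximum angular offset (degrees) of a near outcome
#'   from the segment boundary.
#' @param anticipation_range Two-element interval (s) for the spin duration.
#' @param outcome_duration,numeric_display_duration,iti_duration Phase
#'   durations in seconds.
#' @param rest_duration Pre-task rest recording length (s); its tail serves
#'   as the first trial's baseline window.
#' @param segment_half_width Half-width (degrees) of a wheel segment.
#' @param filler_center_margin Minimum offset (degrees) of a filler stop from
#'   either boundary of the null segment.
#' @param choice_latency_mean,choice_latency_sd,rating_latency_mean,rating_latency_sd
#'   Moments (s) of the log-normal response-latency model for the bet choice
#'   and luck rating.
#' @param latency_floor Minimum latency (s); smaller draws are floored.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(n_win = 19L, n_loss = 19L,
                            n_near_win = 10L, n_near_loss = 10L,
                            n_filler = 18L,
                            payoff_multiplier = 10,
                            bet_levels = seq(10, 90, by = 10),
                            bet_anchor = 50,
                            near_offset_max = 1.8,
                            anticipation_range = c(5.3, 6.9),
                            outcome_duration = 1,
                            numeric_display_duration = 1,
                            iti_duration = 10,
                            rest_duration = 300,
                            segment_half_width = 45,
                            filler_center_margin = 20,
                            choice_latency_mean = 2.91,
                            choice_latency_sd = 2.0,
                            rating_latency_mean = 2.44,
                            rating_latency_sd = 1.75,
                            latency_floor = 0.2) {
  counts <- c(n_win = n_win, n_loss = n_loss, n_near_win = n_near_win,
              n_near_loss = n_near_loss, n_filler = n_filler)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("condition counts must be non-negative integers", call. = FALSE)
  if (payoff_multiplier <= 0) stop("payoff_multiplier must be > 0", call. = FALSE)
  if (near_offset_max <= 0 || near_offset_max > segment_half_width)
    stop("near_offset_max must be in (0, segment_half_width]", call. = FALSE)
  if (any(diff(bet_levels) <= 0) || any(bet_levels <= 0))
    stop("bet_levels must be strictly increasing and positive", call. = FALSE)
  if (bet_anchor < min(bet_levels) || bet_anchor > max(bet_levels))
    stop("bet_anchor must lie within the bet grid", call. = FALSE)
  if (length(anticipation_range) != 2L ||
      anticipation_range[1] >= anticipation_range[2])
    stop("anticipation_range must be an increasing interval", call. = FALSE)
  if (min(outcome_duration, numeric_display_duration, iti_duration,
          rest_duration) <= 0)
    stop("phase durations must be positive", call. = FALSE)
  if (filler_center_margin <= near_offset_max ||
      filler_center_margin > segment_half_width)
    stop("filler_center_margin must be in (near_offset_max, segment_half_width]",
         call. = FALSE)
  structure(list(
    n_win = as.integer(n_win), n_loss = as.integer(n_loss),
    n_near_win = as.integer(n_near_win), n_near_loss = as.integer(n_near_loss),
    n_filler = as.integer(n_filler),
    payoff_multiplier = payoff_multiplier,
    bet_levels = as.numeric(bet_levels), bet_anchor = bet_anchor,
    near_offset_max = near_offset_max,
    anticipation_range = as.numeric(anticipation_range),
    outcome_duration = outcome_duration,
    numeric_display_duration = numeric_display_duration,
    iti_duration = iti_duration, rest_duration = rest_duration,
    segment_half_width = segment_half_width,
    filler_center_margin = filler_center_margin,
    choice_latency_mean = choice_latency_mean,
    choice_latency_sd = choice_latency_sd,
    rating_latency_mean = rating_latency_mean,
    rating_latency_sd = rating_latency_sd,
    latency_floor = latency_floor
  ), class = "schedule_config")
}

condition_levels <- c("win", "loss", "near_win", "near_loss", "filler")

#' Generate a randomized trial schedule
#'
#' Builds the session's trial sequence: exactly the configured number of
#' trials per condition in a fully shuffled order, with outcome geometry
#' assigned and bets initialized at the anchor (a betting agent may overwrite
#' them later; see [simulate_bets()]).
#'
#' @param config A [schedule_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A data frame with one row per trial: `trial_index`, `condition`,
#'   `bet` (pence), `angular_offset` (degrees from the nearest segment
#'   boundary), `obtained_outcome` (signed pence), `counterfactual_magnitude`
#'   (pence), `feedback_sound`.
#' @export
generate_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "schedule_config"))
  maybe_seed(seed)
  counts <- c(config$n_win, config$n_loss, config$n_near_win,
              config$n_near_loss, config$n_filler)
  n <- sum(counts)
  if (n < 1L) stop("total trial count must be positive", call. = FALSE)
  condition <- rep(condition_levels, counts)
  condition <- condition[sample.int(n)]
  schedule <- data.frame(
    trial_index = seq_len(n),
    condition = condition,
    bet = rep(config$bet_anchor, n),
    stringsAsFactors = FALSE
  )
  schedule <- assign_outcome_geometry(schedule, config)
  finalize_outcomes(schedule, config)
}

#' Assign wheel-stop geometry to each trial
#'
#' Draws the angular offset of the spinner's stopping position from the
#' nearest segment boundary: uniform on (0, `near_offset_max`] for near
#' trials, uniform on (`near_offset_max`, `segment_half_width`] for win/loss
#' stops (interior of the win or loss segment), and uniform on
#' \[`filler_center_margin`, `segment_half_width`\] for fillers, keeping them
#' near the centre of the null segment.
#'
#' @param schedule A schedule data frame with a `condition` column.
#' @inheritParams generate_schedule
#' @return The schedule with an `angular_offset` column.
#' @export
assign_outcome_geometry <- function(schedule, config, seed = NULL) {
  maybe_seed(seed)
  n <- nrow(schedule)
  u <- runif(n)
  offset <- numeric(n)
  near <- schedule$condition %in% c("near_win", "near_loss")
  hit <- schedule$condition %in% c("win", "loss")
  fill <- schedule$condition == "filler"
  offset[near] <- config$near_offset_max * (1 - u[near])          # (0, max]
  offset[hit] <- config$near_offset_max +
    (config$segment_half_width - config$near_offset_max) * (1 - u[hit])
  offset[fill] <- config$filler_center_margin +
    (config$segment_half_width - config$filler_center_margin) * u[fill]
  schedule$angular_offset <- offset
  schedule
}

#' Fill in outcomes, counterfactual magnitudes and feedback sounds
#'
#' Recomputes the monetary consequences of each trial from its condition and
#' bet: wins pay `+payoff_multiplier * bet`, losses `-payoff_multiplier *
#' bet`, all other conditions pay nothing; near trials carry the narrowly
#' missed amount as their counterfactual magnitude. Sounds map win to
#' applause, loss to boo, and every null outcome to a thud.
#'
#' @inheritParams assign_outcome_geometry
#' @return The schedule with `obtained_outcome`, `counterfactual_magnitude`
#'   and `feedback_sound` columns.
#' @export
finalize_outcomes <- function(schedule, config) {
  m <- config$payoff_multiplier
  cond <- schedule$condition
  schedule$obtained_outcome <- ifelse(cond == "win", m * schedule$bet,
                               ifelse(cond == "loss", -m * schedule$bet, 0))
  schedule$counterfactual_magnitude <-
    ifelse(cond %in% c("near_win", "near_loss"), m * schedule$bet, 0)
  schedule$feedback_sound <- ifelse(cond == "win", "applause",
                             ifelse(cond == "loss", "boo", "thud"))
  schedule
}

# Unsigned and signed outcome magnitudes (pence) per trial. Unsigned values
# feed the EDA models; signed values (loss and near-loss negative) feed the
# luck-rating models.
trial_magnitudes <- function(schedule) {
  cond <- schedule$condition
  unsigned <- ifelse(cond %in% c("win", "loss"), abs(schedule$obtained_outcome),
              ifelse(cond %in% c("near_win", "near_loss"),
                     schedule$counterfactual_magnitude, 0))
  sign <- ifelse(cond %in% c("loss", "near_loss"), -1, 1)
  list(unsigned = unsigned, signed = sign * unsigned)
}

#' Build the event timeline for a session
#'
#' Lays the trials out in session time. Each trial runs choice (self-paced,
#' latency drawn from a log-normal model), spin/anticipation (uniform on the
#' configured interval), outcome (fixed duration plus the numeric display),
#' luck rating (self-paced), then the intertrial interval. The session opens
#' with the pre-task rest period, so the first trial's choice onset equals
#' `rest_duration` and every trial — including the first — has a 2 s
#' pre-choice window available for baseline extraction.
#'
#' @inheritParams generate_schedule
#' @param schedule A schedule data frame (see [generate_schedule()]).
#' @param latency_model Optional list with functions `choice(n)` and
#'   `rating(n)` returning latency draws in seconds; defaults to log-normal
#'   draws moment-matched to the configured means/SDs, floored at
#'   `latency_floor`.
#' @return A data frame with per-trial `choice_onset`, `spin_onset`,
#'   `outcome_onset`, `rating_onset`, `iti_start`, `iti_end`,
#'   `anticipation_duration`, `choice_latency`, `rating_latency` (all s).
#' @export
build_event_timeline <- function(schedule, config, seed = NULL,
                                 latency_model = NULL) {
  stopifnot(inherits(config, "schedule_config"))
  maybe_seed(seed)
  n <- nrow(schedule)
  if (is.null(latency_model)) {
    latency_model <- list(
      choice = function(k) rlnorm_matched(k, config$choice_latency_mean,
                                          config$choice_latency_sd,
                                          config$latency_floor),
      rating = function(k) rlnorm_matched(k, config$rating_latency_mean,
                                          config$rating_latency_sd,
                                          config$latency_floor)
    )
  }
  choice_lat <- pmax(config$latency_floor, latency_model$choice(n))
  rating_lat <- pmax(config$latency_floor, latency_model$rating(n))
  anticipation <- runif(n, config$anticipation_range[1],
                        config$anticipation_range[2])
  trial_dur <- choice_lat + anticipation + config$outcome_duration +
    config$numeric_display_duration + rating_lat + config$iti_duration
  choice_onset <- config$rest_duration + c(0, cumsum(trial_dur)[-n])
  spin_onset <- choice_onset + choice_lat
  outcome_onset <- spin_onset + anticipation
  rating_onset <- outcome_onset + config$outcome_duration +
    config$numeric_display_duration
  iti_start <- rating_onset + rating_lat
  # defined so that iti_end is bitwise equal to the next trial's choice
  # onset (both are rest + cumsum(trial_dur))
  iti_end <- config$rest_duration + cumsum(trial_dur)
  data.frame(
    trial_index = schedule$trial_index,
    choice_onset = choice_onset, spin_onset = spin_onset,
    outcome_onset = outcome_onset, rating_onset = rating_onset,
    iti_start = iti_start, iti_end = iti_end,
    anticipation_duration = anticipation,
    choice_latency = choice_lat, rating_latency = rating_lat
  )
}

#' Write a BIDS-style events.tsv
#'
#' One row per trial phase (choice, spin, outcome, rating, iti) with onset
#' and duration in seconds plus the trial's condition, bet, outcomes,
#' angular offset and feedback sound.
#'
#' @param schedule,timeline Matching schedule and timeline data frames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(schedule, timeline, path) {
  stopifnot(nrow(schedule) == nrow(timeline))
  phases <- list(
    c("choice", "choice_onset", "choice_latency"),
    c("spin", "spin_onset", "anticipation_duration"),
    c("outcome", "outcome_onset", NA),
    c("rating", "rating_onset", "rating_latency"),
    c("iti", "iti_start", NA)
  )
  rows <- lapply(phases, function(ph) {
    dur <- if (ph[1] == "outcome") {
      timeline$rating_onset - timeline$outcome_onset
    } else if (ph[1] == "iti") {
      timeline$iti_end - timeline$iti_start
    } else {
      timeline[[ph[3]]]
    }
    data.frame(
      onset = timeline[[ph[2]]], duration = dur,
      trial_index = schedule$trial_index, phase = ph[1],
      condition = schedule$condition, bet_pence = schedule$bet,
      outcome_pence = schedule$obtained_outcome,
      counterfactual_pence = schedule$counterfactual_magnitude,
      angular_offset_deg = schedule$angular_offset,
      sound = schedule$feedback_sound,
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset), , drop = FALSE]
  ev$onset <- sprintf("%.6f", ev$onset)
  ev$duration <- sprintf("%.6f", ev$duration)
  ev$angular_offset_deg <- sprintf("%.6f", ev$angular_offset_deg)
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-trial behavioural table
#'
#' Trial-keyed behavioural data that complements events.tsv: bets,
#' outcomes, counterfactual magnitudes and luck ratings.
#'
#' @param schedule A schedule data frame with bets (and, if simulated,
#'   luck ratings) assigned.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_tsv <- function(schedule, path) {
  d <- data.frame(
    trial_index = schedule$trial_index,
    condition = schedule$condition,
    bet_pence = schedule$bet,
    outcome_pence = schedule$obtained_outcome,
    counterfactual_pence = schedule$counterfactual_magnitude,
    luck_rating = if ("luck_rating" %in% names(schedule))
      schedule$luck_rating else NA_integer_,
    stringsAsFactors = FALSE
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a behavioural table written by [write_behavior_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A data frame keyed by `trial_index`.
#' @export
read_behavior_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d[order(d$trial_index), ]
}

#' Read an events.tsv back into schedule and timeline tables
#'
#' Inverse of [write_events_tsv()] up to numeric formatting precision.
#'
#' @param path Path to an events.tsv written by [write_events_tsv()].
#' @return A list with elements `schedule` and `timeline`.
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_index", "phase", "condition",
            "bet_pence", "outcome_pence", "counterfactual_pence",
            "angular_offset_deg", "sound")
  if (!all(need %in% names(ev)))
    stop("events file is missing required columns", call. = FALSE)
  ev <- ev[order(ev$trial_index, ev$onset), ]
  one <- function(phase, col) {
    x <- ev[ev$phase == phase, ]
    x <- x[order(x$trial_index), ]
    x[[col]]
  }
  ch <- ev[ev$phase == "choice", ]
  ch <- ch[order(ch$trial_index), ]
  schedule <- data.frame(
    trial_index = ch$trial_index, condition = ch$condition,
    bet = ch$bet_pence, angular_offset = ch$angular_offset_deg,
    obtained_outcome = ch$outcome_pence,
    counterfactual_magnitude = ch$counterfactual_pence,
    feedback_sound = ch$sound, stringsAsFactors = FALSE
  )
  timeline <- data.frame(
    trial_index = ch$trial_index,
    choice_onset = one("choice", "onset"),
    spin_onset = one("spin", "onset"),
    outcome_onset = one("outcome", "onset"),
    rating_onset = one("rating", "onset"),
    iti_start = one("iti", "onset"),
    iti_end = one("iti", "onset") + one("iti", "duration"),
    anticipation_duration = one("spin", "duration"),
    choice_latency = one("choice", "duration"),
    rating_latency = one("rating", "duration")
  )
  list(schedule = schedule, timeline = timeline)
}
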