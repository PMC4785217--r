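# Shared fixtures: noise-free generative settings and hand-built sessions.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# Amplitude model with every stochastic component switched off.
amp_noise_free <- function(...) {
  amplitude_model(participant_intercept_sd = 0, participant_gain_sd = 0,
                  trial_noise_sd = 0, summary_noise_sd = 0,
                  tonic_sd = 0, drift_amplitude = 0,
                  measurement_noise_sd = 0, ...)
}

policy_deterministic <- function(...) bet_policy(shift_sd = 0, ...)

luck_deterministic <- function(...) luck_params(rating_noise_sd = 0, ...)

# Build a schedule by hand from condition and bet vectors.
make_schedule <- function(conditions, bets, cfg = schedule_config()) {
  s <- data.frame(trial_index = seq_along(conditions),
                  condition = conditions, bet = bets,
                  stringsAsFactors = FALSE)
  s$angular_offset <- ifelse(s$condition %in% c("near_win", "near_loss"),
                             1, 30)
  finalize_outcomes(s, cfg)
}

# Trial-record rows generated directly from a linear model, bypassing
# traces: y = intercept_i + slope * magnitude (exact, noise-free).
make_linear_records <- function(slope, intercepts, magnitudes,
                                response = "outcome_eda",
                                predictor = "magnitude",
                                condition = "loss") {
  do.call(rbind, lapply(seq_along(intercepts), function(i) {
    data.frame(participant_id = sprintf("p%02d", i),
               trial_index = seq_along(magnitudes),
               condition = condition, bet = magnitudes / 10,
               outcome_pence = magnitudes,
               magnitude = magnitudes, magnitude_signed = magnitudes,
               baseline_selection = 0, baseline_outcome = 0,
               selection_eda = intercepts[i] + slope * magnitudes / 10,
               outcome_eda = intercepts[i] + slope * magnitudes,
               luck_rating = 5L, included = TRUE, missing = FALSE,
               stringsAsFactors = FALSE)
  }))
}
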