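#' Generative model for skin-conductance response amplitudes
#'
#' Ground-truth model for the synthetic cohort. All amplitudes are expressed
#' in log10-conductance units and the trace is assembled as
#' `10^(tonic + drift + sum of phasic responses)`, so that the analysis-side
#' log10 transform makes the modelled quantities exactly linear in bet and
#' outcome magnitude. Each event's amplitude is
#' `gain_i * (intercept + slope * magnitude + u_i + noise)`, floored at 0,
#' where `gain_i` is a participant-specific multiplicative responsiveness
#' factor (log-normal, mean 1) and `u_i` an additive participant offset;
#' trial noise and the offset sit inside the gain bracket, i.e. amplitude
#' variability scales with a participant's overall responsiveness.
#' Default slopes are the empirical estimates the pipeline is designed to
#' recover: selection 6.30e-4 per pence of bet; win 2.625e-5, loss 8.35e-5,
#' near-win 6.34e-5, near-loss 7.23e-5 per pence of (counterfactual) outcome.
#'
#' @param selection_slope log10-uS per pence of bet at the choice phase.
#' @param win_slope,loss_slope,near_win_slope,near_loss_slope log10-uS per
#'   pence of outcome magnitude at the outcome phase.
#' @param selection_intercept,outcome_intercept Baseline phasic amplitudes
#'   (log10-uS) at zero magnitude.
#' @param participant_intercept_sd SD of the additive participant amplitude
#'   offset (log10-uS).
#' @param participant_gain_sd Log-scale SD of the multiplicative participant
#'   gain (mean fixed at 1).
#' @param trial_noise_sd SD of trial-to-trial amplitude noise (log10-uS);
#'   amplitudes are floored at 0 after noise.
#' @param summary_noise_sd Summary-mode stand-in (log10-uS) for the residual
#'   baseline/drift variability a full trace adds to each phase summary.
#' @param scr_rise,scr_decay Bi-exponential response time constants (s).
#' @param scr_latency Event-to-response onset latency (s).
#' @param tonic_log10 Mean tonic level, log10 microsiemens.
#' @param tonic_sd Between-participant SD of the tonic level (log10-uS).
#' @param drift_amplitude,drift_period Slow sinusoidal tonic drift
#'   (log10-uS, s).
#' @param measurement_noise_sd White measurement noise on each sample
#'   (log10-uS).
#' @param sampling_rate Trace sampling rate in Hz (100 or 1000).
#' @return An object of class `amplitude_model`.
#' @export
amplitude_model <- function(selection_slope = 6.30e-4,
                            win_slope = 2.625e-5, loss_slope = 8.35e-5,
                            near_win_slope = 6.34e-5, near_loss_slope = 7.23e-5,
                            selection_intercept = 0.02,
                            outcome_intercept = 0.02,
                            participant_intercept_sd = 0.005,
                            participant_gain_sd = 0.6,
                            trial_noise_sd = 0.005,
                            summary_noise_sd = 0.025,
                            scr_rise = 0.75, scr_decay = 4.0,
                            scr_latency = 1.0,
                            tonic_log10 = 0.7, tonic_sd = 0.15,
                            drift_amplitude = 0.05, drift_period = 120,
                            measurement_noise_sd = 0.005,
                            sampling_rate = 100) {
  if (any(c(participant_intercept_sd, participant_gain_sd, trial_noise_sd,
            summary_noise_sd, tonic_sd, measurement_noise_sd) < 0))
    stop("all SDs must be >= 0", call. = FALSE)
  if (scr_rise >= scr_decay)
    stop("scr_rise must be smaller than scr_decay", call. = FALSE)
  if (!sampling_rate %in% c(100, 1000))
    stop("sampling_rate must be 100 or 1000 Hz", call. = FALSE)
  structure(mget(names(formals())), class = "amplitude_model")
}

#' Canonical phasic skin-conductance response kernel
#'
#' Bi-exponential unit-peak response
#' `h(t) = c * (exp(-t / decay) - exp(-t / rise))`, normalized so its
#' maximum is 1; `h(0) = 0` and `h(t) = 0` for `t < 0`.
#'
#' @param t Time since response onset (s); vectorized.
#' @param rise,decay Time constants in seconds, `rise < decay`.
#' @return Kernel values in `[0, 1]`.
#' @export
scr_kernel <- function(t, rise = 0.75, decay = 4.0) {
  if (rise >= decay) stop("rise must be smaller than decay", call. = FALSE)
  peak <- scr_peak_time(rise, decay)
  c0 <- 1 / (exp(-peak / decay) - exp(-peak / rise))
  h <- c0 * (exp(-t / decay) - exp(-t / rise))
  h[t < 0] <- 0
  h
}

#' Peak time of the bi-exponential response kernel
#'
#' Closed-form argmax `(log decay - log rise) / (1/rise - 1/decay)`.
#'
#' @inheritParams scr_kernel
#' @return Peak time in seconds.
#' @export
scr_peak_time <- function(rise = 0.75, decay = 4.0) {
  if (rise >= decay) stop("rise must be smaller than decay", call. = FALSE)
  (log(decay) - log(rise)) / (1 / rise - 1 / decay)
}

# Mean of the unit-peak kernel over each analysis bin, accounting for the
# response latency, by exact integration; and the summary attenuation
# factor kappa = max over the summary bins. This is the closed-form factor
# linking a generative amplitude to its phase summary.
kernel_bin_means <- function(amp, pcfg) {
  peak <- scr_peak_time(amp$scr_rise, amp$scr_decay)
  c0 <- 1 / (exp(-peak / amp$scr_decay) - exp(-peak / amp$scr_rise))
  antider <- function(u) {
    c0 * (-amp$scr_decay * exp(-u / amp$scr_decay) +
            amp$scr_rise * exp(-u / amp$scr_rise))
  }
  vapply(seq_len(pcfg$n_bins), function(k) {
    a <- max(0, (k - 1) * pcfg$bin_width - amp$scr_latency)
    b <- max(0, k * pcfg$bin_width - amp$scr_latency)
    if (b <= a) return(0)
    (antider(b) - antider(a)) / pcfg$bin_width
  }, numeric(1))
}

#' Closed-form attenuation of an amplitude in the phase summary
#'
#' The max-change summary averages the response kernel over 2-s bins, so a
#' phasic response of amplitude `a` contributes `kappa * a` to the summary,
#' where `kappa` is the largest mean kernel value over the summary bins.
#' Used to map summary-scale slope estimates back to amplitude scale in
#' recovery studies.
#'
#' @param amp An [amplitude_model()].
#' @param pcfg A [preprocess_config()].
#' @return The scalar attenuation factor `kappa`.
#' @export
kernel_bin_attenuation <- function(amp, pcfg = preprocess_config()) {
  max(kernel_bin_means(amp, pcfg)[pcfg$summary_bins])
}

# Draw participant-level effects, in a fixed order so that seeded streams
# are stable: gain, additive offset, tonic level, drift phase.
draw_participant_effects <- function(amp) {
  gain <- exp(rnorm(1, -amp$participant_gain_sd^2 / 2, amp$participant_gain_sd))
  offset <- rnorm(1, 0, amp$participant_intercept_sd)
  tonic <- rnorm(1, amp$tonic_log10, amp$tonic_sd)
  phase <- runif(1, 0, 2 * pi)
  list(gain = gain, offset = offset, tonic = tonic, drift_phase = phase)
}

# Event amplitudes (log10-uS, floored at 0) for one participant's session.
# Returns choice- and outcome-event amplitudes per trial.
draw_event_amplitudes <- function(schedule, amp, effects) {
  n <- nrow(schedule)
  mag <- trial_magnitudes(schedule)$unsigned
  slope <- c(win = amp$win_slope, loss = amp$loss_slope,
             near_win = amp$near_win_slope, near_loss = amp$near_loss_slope,
             filler = 0)[schedule$condition]
  noise <- function() {
    if (amp$trial_noise_sd > 0) rnorm(n, 0, amp$trial_noise_sd) else numeric(n)
  }
  choice <- effects$gain * (amp$selection_intercept +
                              amp$selection_slope * schedule$bet +
                              effects$offset + noise())
  outcome <- effects$gain * (amp$outcome_intercept + slope * mag +
                               effects$offset + noise())
  list(choice = pmax(0, choice), outcome = pmax(0, outcome))
}

#' Synthesize a continuous skin-conductance trace for one session
#'
#' Builds the log10-domain signal as tonic level + slow sinusoidal drift +
#' white measurement noise + phasic responses at each choice and outcome
#' onset (amplitudes from the generative model, bi-exponential kernel with a
#' fixed onset latency), then exponentiates to microsiemens.
#'
#' @param timeline,schedule Matching timeline and schedule for the session.
#' @param amp An [amplitude_model()].
#' @param seed Optional integer seed.
#' @param effects Optional pre-drawn participant effects (internal use).
#' @return An object of class `eda_trace`: list with `values` (microsiemens),
#'   `sampling_rate` (Hz), `t0` (s) and the ground-truth `amplitudes`.
#' @export
synthesize_trace <- function(timeline, schedule, amp, seed = NULL,
                             effects = NULL) {
  stopifnot(inherits(amp, "amplitude_model"))
  maybe_seed(seed)
  if (is.null(effects)) effects <- draw_participant_effects(amp)
  amps <- draw_event_amplitudes(schedule, amp, effects)
  rate <- amp$sampling_rate
  duration <- timeline$iti_end[nrow(timeline)]
  n <- floor(duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  logv <- rep(effects$tonic, n)
  if (amp$drift_amplitude > 0) {
    logv <- logv + amp$drift_amplitude *
      sin(2 * pi * t / amp$drift_period + effects$drift_phase)
  }
  if (amp$measurement_noise_sd > 0) {
    logv <- logv + rnorm(n, 0, amp$measurement_noise_sd)
  }
  support <- ceiling((amp$scr_latency + 10 * amp$scr_decay) * rate)
  add_event <- function(logv, onset, a) {
    if (a <= 0) return(logv)
    w <- sample_window(onset, onset + support / rate, rate, t0 = 0, n = n)
    if (is.null(w)) w <- c(ceiling(onset * rate - 1e-9) + 1L, n)
    idx <- w[1]:min(w[2], n)
    u <- t[idx] - onset - amp$scr_latency
    logv[idx] <- logv[idx] + a * scr_kernel(u, amp$scr_rise, amp$scr_decay)
    logv
  }
  for (i in seq_len(nrow(schedule))) {
    logv <- add_event(logv, timeline$choice_onset[i], amps$choice[i])
    logv <- add_event(logv, timeline$outcome_onset[i], amps$outcome[i])
  }
  structure(list(values = 10^logv, sampling_rate = rate, t0 = 0,
                 unit = "uS", amplitudes = amps, effects = effects),
            class = "eda_trace")
}

#' Construct an EDA trace object from raw samples
#'
#' @param values Conductance samples in microsiemens (must be positive).
#' @param sampling_rate Sampling rate in Hz.
#' @param t0 Session time of the first sample (s).
#' @param unit Sample unit label.
#' @return An object of class `eda_trace`.
#' @export
eda_trace <- function(values, sampling_rate, t0 = 0, unit = "uS") {
  if (any(!is.finite(values))) stop("trace values must be finite", call. = FALSE)
  structure(list(values = as.numeric(values), sampling_rate = sampling_rate,
                 t0 = t0, unit = unit),
            class = "eda_trace")
}

#' @export
print.eda_trace <- function(x, ...) {
  cat(sprintf("<eda_trace> %d samples @ %g Hz (%.1f s), unit %s\n",
              length(x$values), x$sampling_rate,
              length(x$values) / x$sampling_rate, x$unit))
  invisible(x)
}

#' Write a continuous physiological trace with a JSON sidecar
#'
#' Writes a gzipped two-column tab-separated file (`time_s`,
#' `conductance_uS`) plus a JSON sidecar holding the sampling rate,
#' participant id and generating seed.
#'
#' @param trace An [eda_trace()].
#' @param path Output path ending in `.tsv.gz`.
#' @param participant_id,seed Metadata recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_physio <- function(trace, path, participant_id = NA, seed = NA) {
  stopifnot(inherits(trace, "eda_trace"))
  t <- trace$t0 + (seq_along(trace$values) - 1L) / trace$sampling_rate
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines("time_s\tconductance_uS", con)
  writeLines(sprintf("%.4f\t%.8g", t, trace$values), con)
  sidecar <- sub("\\.tsv\\.gz$", ".json", path)
  jsonlite::write_json(list(sampling_rate_hz = trace$sampling_rate,
                            participant_id = participant_id,
                            seed = seed, t0_s = trace$t0,
                            unit = trace$unit),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a continuous physiological trace and its JSON sidecar
#'
#' @param path Path to a `.tsv.gz` written by [write_physio()].
#' @return An [eda_trace()] with sidecar metadata attached as attributes.
#' @export
read_physio <- function(path) {
  d <- read.delim(gzfile(path))
  sidecar <- sub("\\.tsv\\.gz$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  rate <- meta$sampling_rate_hz
  if (is.null(rate)) {
    rate <- round(1 / stats::median(diff(d$time_s)))
  }
  tr <- eda_trace(d$conductance_uS, rate, t0 = d$time_s[1])
  attr(tr, "participant_id") <- meta$participant_id
  attr(tr, "seed") <- meta$seed
  tr
}
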