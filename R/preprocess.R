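#' EDA preprocessing configuration
#'
#' Parameters of the trial-locked EDA reduction: resampling rate, log
#' transform floor, the 2-s end-of-ITI baseline window, the 4 x 2 s
#' post-onset bins, the bins entering the max-change summary (bins 2-4,
#' i.e. 2-8 s post onset), and the flat-trace nonresponder screen.
#'
#' @param target_rate Analysis sampling rate in Hz.
#' @param log_floor Floor in microsiemens applied before the log10 transform.
#' @param baseline_window Baseline window length (s), taken from the end of
#'   the preceding intertrial interval.
#' @param n_bins Number of post-onset bins.
#' @param bin_width Bin width in seconds.
#' @param summary_bins Indices of the bins entering the max-change summary.
#' @param nonresponder_min_sd Minimum across-trial SD of the outcome summary
#'   (log10 units) for a participant to count as an electrodermal responder.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 100, log_floor = 1e-3,
                              baseline_window = 2, n_bins = 4L,
                              bin_width = 2, summary_bins = 2:4,
                              nonresponder_min_sd = 1e-4) {
  if (min(target_rate, baseline_window, bin_width) <= 0 || n_bins < 1)
    stop("rates, window lengths and bin counts must be positive", call. = FALSE)
  if (!all(summary_bins %in% seq_len(n_bins)))
    stop("summary_bins must be a subset of 1..n_bins", call. = FALSE)
  if (log_floor <= 0) stop("log_floor must be > 0", call. = FALSE)
  structure(list(target_rate = target_rate, log_floor = log_floor,
                 baseline_window = baseline_window, n_bins = as.integer(n_bins),
                 bin_width = bin_width, summary_bins = as.integer(summary_bins),
                 nonresponder_min_sd = nonresponder_min_sd),
            class = "preprocess_config")
}

#' Resample a trace to a lower rate
#'
#' Anti-alias filtered decimation: a zero-phase linear-phase FIR low-pass
#' (cutoff at 80% of the target Nyquist frequency, designed with
#' [signal::fir1()]) is applied with reflection padding, then every q-th
#' sample is kept. The source rate must be an integer multiple of the
#' target rate.
#'
#' @param trace An [eda_trace()].
#' @param target_rate Target sampling rate in Hz.
#' @return The resampled [eda_trace()].
#' @export
resample_trace <- function(trace, target_rate = 100) {
  stopifnot(inherits(trace, "eda_trace"))
  if (trace$sampling_rate < target_rate)
    stop("trace rate is below the target rate", call. = FALSE)
  q <- trace$sampling_rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("source rate must be an integer multiple of the target rate",
         call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(trace)
  x <- trace$values
  ord <- 10L * q                       # even order -> symmetric odd-length FIR
  h <- signal::fir1(ord, 0.8 / q)
  h <- h / sum(h)
  m <- min(ord, length(x) - 1L)
  xp <- c(rev(x[2:(m + 1L)]), x, rev(x[(length(x) - m):(length(x) - 1L)]))
  y <- stats::filter(xp, h, sides = 2)
  y <- as.numeric(y[(m + 1L):(m + length(x))])
  eda_trace(y[seq(1L, length(y), by = q)], target_rate, t0 = trace$t0,
            unit = trace$unit)
}

#' Log-transform a conductance trace
#'
#' Elementwise `log10(max(value, log_floor))`; the floor guards against
#' non-positive samples and sits far below the physiological range.
#'
#' @param trace An [eda_trace()] in microsiemens, or a numeric vector.
#' @param log_floor Floor in microsiemens.
#' @return The trace (or vector) in log10 units.
#' @export
log_transform <- function(trace, log_floor = 1e-3) {
  if (inherits(trace, "eda_trace")) {
    out <- trace
    out$values <- log10(pmax(trace$values, log_floor))
    out$unit <- "log10uS"
    return(out)
  }
  log10(pmax(trace, log_floor))
}

#' Trial baseline from the end of the intertrial interval
#'
#' Mean of the log-transformed samples over the `baseline_window` seconds
#' ending at `iti_end` (half-open window `[iti_end - window, iti_end)`).
#' Because each trial's choice onset coincides with the preceding ITI's end,
#' passing the choice onset yields the trial's own preceding-ITI baseline;
#' for the first trial the window falls in the pre-task rest tail.
#'
#' @param trace A log-transformed [eda_trace()].
#' @param iti_end End of the intertrial interval (s, session time).
#' @param baseline_window Window length in seconds.
#' @return Mean log10 conductance over the window.
#' @export
baseline_value <- function(trace, iti_end, baseline_window = 2) {
  stopifnot(inherits(trace, "eda_trace"))
  w <- sample_window(iti_end - baseline_window, iti_end,
                     trace$sampling_rate, trace$t0, length(trace$values))
  if (is.null(w)) stop("baseline window lies outside the trace", call. = FALSE)
  mean(trace$values[w[1]:w[2]])
}

#' Max-change phase summary
#'
#' Averages the log-transformed signal in `n_bins` half-open bins of
#' `bin_width` seconds from `onset`, then returns the maximum of
#' (bin mean - baseline) over the summary bins (bins 2-4 by default, 2-8 s
#' post onset). The value is signed: a trace that only decreases yields a
#' negative summary. Returns `NA` if the trace does not cover the full
#' binning window.
#'
#' @param trace A log-transformed [eda_trace()].
#' @param onset Phase onset in session time (s).
#' @param baseline Baseline value in log10 units (see [baseline_value()]).
#' @param config A [preprocess_config()].
#' @return The signed summary in log10 units, or `NA` if truncated.
#' @export
phase_summary <- function(trace, onset, baseline,
                          config = preprocess_config()) {
  stopifnot(inherits(trace, "eda_trace"))
  means <- vapply(seq_len(config$n_bins), function(k) {
    w <- sample_window(onset + (k - 1) * config$bin_width,
                       onset + k * config$bin_width,
                       trace$sampling_rate, trace$t0, length(trace$values))
    if (is.null(w)) return(NA_real_)
    mean(trace$values[w[1]:w[2]])
  }, numeric(1))
  if (anyNA(means[config$summary_bins])) return(NA_real_)
  max(means[config$summary_bins] - baseline)
}

#' Extract the trial-level analysis table for one participant
#'
#' Applies the full reduction to one session: optional resampling to the
#' target rate, log10 transform, per-trial preceding-ITI baseline, and the
#' max-change summary time-locked separately to the choice and outcome
#' onsets. Filler trials are retained but flagged `included = FALSE`.
#'
#' @param trace An [eda_trace()] in microsiemens.
#' @param schedule,timeline The session's schedule and timeline.
#' @param participant_id Identifier copied into the records.
#' @param config A [preprocess_config()].
#' @return A data frame of trial records: `participant_id`, `trial_index`,
#'   `condition`, `bet`, `outcome_pence`, `magnitude`, `magnitude_signed`,
#'   `baseline_selection`, `baseline_outcome`, `selection_eda`,
#'   `outcome_eda`, `luck_rating`, `included`, `missing`.
#' @export
trial_records <- function(trace, schedule, timeline, participant_id = "p1",
                          config = preprocess_config()) {
  stopifnot(nrow(schedule) == nrow(timeline))
  if (trace$sampling_rate != config$target_rate) {
    trace <- resample_trace(trace, config$target_rate)
  }
  lt <- log_transform(trace, config$log_floor)
  n <- nrow(schedule)
  base <- vapply(seq_len(n), function(i) {
    baseline_value(lt, timeline$choice_onset[i], config$baseline_window)
  }, numeric(1))
  sel <- vapply(seq_len(n), function(i) {
    phase_summary(lt, timeline$choice_onset[i], base[i], config)
  }, numeric(1))
  out <- vapply(seq_len(n), function(i) {
    phase_summary(lt, timeline$outcome_onset[i], base[i], config)
  }, numeric(1))
  mags <- trial_magnitudes(schedule)
  data.frame(
    participant_id = participant_id,
    trial_index = schedule$trial_index,
    condition = schedule$condition,
    bet = schedule$bet,
    outcome_pence = schedule$obtained_outcome,
    magnitude = mags$unsigned,
    magnitude_signed = mags$signed,
    baseline_selection = base,
    baseline_outcome = base,
    selection_eda = sel,
    outcome_eda = out,
    luck_rating = if ("luck_rating" %in% names(schedule))
      schedule$luck_rating else NA_integer_,
    included = schedule$condition != "filler",
    missing = is.na(sel) | is.na(out),
    stringsAsFactors = FALSE
  )
}

#' Extract trial records for a whole cohort
#'
#' @param traces Named list of [eda_trace()] objects, one per participant.
#' @param schedules,timelines Named lists aligned with `traces`.
#' @param config A [preprocess_config()].
#' @return One combined trial-record data frame (see [trial_records()]).
#' @export
extract_trial_table <- function(traces, schedules, timelines,
                                config = preprocess_config()) {
  ids <- names(traces)
  if (is.null(ids)) ids <- paste0("p", seq_along(traces))
  do.call(rbind, lapply(seq_along(traces), function(i) {
    trial_records(traces[[i]], schedules[[i]], timelines[[i]], ids[i], config)
  }))
}

#' Screen for electrodermal nonresponders
#'
#' Excludes participants whose across-trial SD of the outcome-locked summary
#' falls below `nonresponder_min_sd` — i.e. participants with no discernible
#' phasic EDA.
#'
#' @param records A trial-record table (see [trial_records()]).
#' @param config A [preprocess_config()].
#' @return A list with `included` and `excluded` participant ids and the
#'   per-participant summary `sd`.
#' @export
screen_nonresponders <- function(records, config = preprocess_config()) {
  if (nrow(records) == 0) stop("no trial records supplied", call. = FALSE)
  sds <- tapply(records$outcome_eda, records$participant_id,
                function(x) stats::sd(x, na.rm = TRUE))
  sds[is.na(sds)] <- 0
  excluded <- names(sds)[sds < config$nonresponder_min_sd]
  included <- setdiff(names(sds), excluded)
  if (length(included) == 0)
    stop("all participants screened out as nonresponders (max SD = ",
         format(max(sds)), ")", call. = FALSE)
  list(included = included, excluded = excluded, sd = sds)
}

#' Preprocess one recorded session from files
#'
#' Reads a BIDS-style events.tsv and a gzipped physio trace and returns the
#' trial-record table.
#'
#' @param events_path Path to events.tsv (see [write_events_tsv()]).
#' @param physio_path Path to the `.tsv.gz` trace (see [write_physio()]).
#' @param behavior_path Optional path to the behavioural table (see
#'   [write_behavior_tsv()]); supplies the luck ratings.
#' @param participant_id Identifier for the records; defaults to the
#'   sidecar's participant id if present.
#' @param config A [preprocess_config()].
#' @return A trial-record data frame.
#' @export
preprocess_session <- function(events_path, physio_path,
                               behavior_path = NULL,
                               participant_id = NULL,
                               config = preprocess_config()) {
  ev <- read_events_tsv(events_path)
  tr <- read_physio(physio_path)
  if (!is.null(behavior_path)) {
    beh <- read_behavior_tsv(behavior_path)
    i <- match(ev$schedule$trial_index, beh$trial_index)
    ev$schedule$luck_rating <- as.integer(beh$luck_rating[i])
  }
  if (is.null(participant_id)) {
    participant_id <- attr(tr, "participant_id")
    if (is.null(participant_id) || is.na(participant_id)) participant_id <- "p1"
  }
  trial_records(tr, ev$schedule, ev$timeline, participant_id, config)
}
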