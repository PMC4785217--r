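#' Full experiment configuration
#'
#' Bundles the schedule, betting agent, amplitude model, luck model and
#' preprocessing configurations with the cohort size and master seed.
#' Defaults describe the study conditions the pipeline emulates: 50
#' analysed participants, 76 trials each.
#'
#' @param schedule A [schedule_config()].
#' @param policy A [bet_policy()]; its grid defaults to the schedule's.
#' @param amplitude An [amplitude_model()].
#' @param luck A [luck_params()].
#' @param preprocess A [preprocess_config()].
#' @param n_participants Cohort size (>= 2).
#' @param master_seed Integer master seed; all per-participant and
#'   per-replicate seeds are derived from it.
#' @param mode `"trace"` simulates and preprocesses full conductance
#'   traces; `"summary"` generates the trial summaries directly from the
#'   generative model and the closed-form kernel attenuation (fast path for
#'   replicate studies).
#' @return An object of class `run_config`.
#' @export
run_config <- function(schedule = schedule_config(),
                       policy = bet_policy(anchor = schedule$bet_anchor,
                                           grid = schedule$bet_levels),
                       amplitude = amplitude_model(),
                       luck = luck_params(),
                       preprocess = preprocess_config(),
                       n_participants = 50L,
                       master_seed = 1L,
                       mode = c("trace", "summary")) {
  if (n_participants < 2) stop("n_participants must be >= 2", call. = FALSE)
  structure(list(schedule = schedule, policy = policy, amplitude = amplitude,
                 luck = luck, preprocess = preprocess,
                 n_participants = as.integer(n_participants),
                 master_seed = as.integer(master_seed),
                 mode = match.arg(mode)),
            class = "run_config")
}

#' Simulate one participant's session
#'
#' Draws the schedule, bets, luck ratings, event timeline and (in trace
#' mode) the continuous conductance trace from one seed.
#'
#' @param rc A [run_config()].
#' @param seed Participant seed.
#' @param participant_id Identifier.
#' @param with_trace Synthesize the continuous trace (TRUE for trace mode).
#' @return A list with `schedule`, `timeline`, and (if requested) `trace`.
#' @export
simulate_participant <- function(rc, seed, participant_id = "p1",
                                 with_trace = TRUE) {
  set.seed(as.integer(seed))
  schedule <- generate_schedule(rc$schedule)
  schedule <- simulate_bets(schedule, rc$policy, rc$schedule)
  schedule <- simulate_luck_ratings(schedule, rc$luck)
  timeline <- build_event_timeline(schedule, rc$schedule)
  out <- list(participant_id = participant_id, schedule = schedule,
              timeline = timeline)
  if (with_trace) {
    out$trace <- synthesize_trace(timeline, schedule, rc$amplitude)
  }
  out
}

# Summary-mode cohort: trial records generated directly in the analysis
# space. Each participant's schedule order is drawn from the same
# per-participant seed stream as trace mode (so the two modes agree
# trial-for-trial when all noise sources are off); bets, luck, amplitudes
# and summary noise are then drawn vectorized from a cohort-level stream.
simulate_cohort_records <- function(rc, seed) {
  n_p <- rc$n_participants
  seeds <- derive_seeds(seed, n_p + 1L)
  cfg <- rc$schedule
  counts <- c(cfg$n_win, cfg$n_loss, cfg$n_near_win, cfg$n_near_loss,
              cfg$n_filler)
  n_t <- sum(counts)
  if (n_t < 1L) stop("total trial count must be positive", call. = FALSE)
  base <- rep(condition_levels, counts)
  cond <- matrix("", n_t, n_p)
  for (i in seq_len(n_p)) {
    set.seed(seeds[i])
    cond[, i] <- base[sample.int(n_t)]
  }
  set.seed(seeds[n_p + 1L])
  bet <- simulate_bets_matrix(cond, rc$policy)
  m <- cfg$payoff_multiplier
  outcome <- ifelse(cond == "win", m * bet, ifelse(cond == "loss", -m * bet, 0))
  near <- cond %in% c("near_win", "near_loss")
  mag <- ifelse(cond %in% c("win", "loss"), abs(outcome), 0)
  mag[near] <- (m * bet)[near]
  sign <- ifelse(cond %in% c("loss", "near_loss"), -1, 1)

  amp <- rc$amplitude
  gain <- exp(rnorm(n_p, -amp$participant_gain_sd^2 / 2,
                    amp$participant_gain_sd))
  offset <- rnorm(n_p, 0, amp$participant_intercept_sd)
  gm <- matrix(gain, n_t, n_p, byrow = TRUE)
  om <- matrix(offset, n_t, n_p, byrow = TRUE)
  slope_lut <- c(win = amp$win_slope, loss = amp$loss_slope,
                 near_win = amp$near_win_slope,
                 near_loss = amp$near_loss_slope, filler = 0)
  cond_slope <- matrix(slope_lut[cond], n_t, n_p)
  tn <- function() {
    if (amp$trial_noise_sd > 0) {
      matrix(rnorm(n_t * n_p, 0, amp$trial_noise_sd), n_t, n_p)
    } else 0
  }
  amp_choice <- pmax(0, gm * (amp$selection_intercept +
                                amp$selection_slope * bet + om + tn()))
  amp_out <- pmax(0, gm * (amp$outcome_intercept + cond_slope * mag +
                             om + tn()))
  kappa <- kernel_bin_attenuation(amp, rc$preprocess)
  sn <- function() {
    if (amp$summary_noise_sd > 0) {
      matrix(rnorm(n_t * n_p, 0, amp$summary_noise_sd), n_t, n_p)
    } else 0
  }
  sel_eda <- kappa * amp_choice + sn()
  out_eda <- kappa * amp_out + sn()

  lp <- rc$luck
  luck_lut <- luck_condition_slopes(lp)
  lmag <- if (lp$magnitude_coding == "signed") sign * mag else mag
  ln <- if (lp$rating_noise_sd > 0) {
    matrix(rnorm(n_t * n_p, 0, lp$rating_noise_sd), n_t, n_p)
  } else 0
  luck <- pmin(9, pmax(1, round(lp$baseline_rating +
                                  matrix(luck_lut[cond], n_t, n_p) * lmag +
                                  ln)))

  ids <- sprintf("p%02d", seq_len(n_p))
  data.frame(
    participant_id = rep(ids, each = n_t),
    trial_index = rep(seq_len(n_t), n_p),
    condition = as.vector(cond),
    bet = as.vector(bet),
    outcome_pence = as.vector(outcome),
    magnitude = as.vector(mag),
    magnitude_signed = as.vector(sign * mag),
    baseline_selection = 0, baseline_outcome = 0,
    selection_eda = as.vector(sel_eda),
    outcome_eda = as.vector(out_eda),
    luck_rating = as.integer(luck),
    included = as.vector(cond != "filler"),
    missing = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort and extract its trial table
#'
#' In trace mode each participant's continuous trace is synthesized and run
#' through the full preprocessing chain; in summary mode the trial
#' summaries are generated directly (see [run_config()]).
#'
#' @param rc A [run_config()].
#' @param seed Cohort seed (defaults to the config's master seed).
#' @param keep_raw In trace mode, also return the raw per-participant
#'   sessions (schedules, timelines, traces).
#' @return A trial-record data frame; with `keep_raw`, a list
#'   `(records, sessions)`.
#' @export
simulate_cohort <- function(rc, seed = rc$master_seed, keep_raw = FALSE) {
  if (rc$mode == "summary") {
    return(simulate_cohort_records(rc, seed))
  }
  seeds <- derive_seeds(seed, rc$n_participants + 1L)
  ids <- sprintf("p%02d", seq_len(rc$n_participants))
  sessions <- lapply(seq_len(rc$n_participants), function(i) {
    simulate_participant(rc, seeds[i], ids[i], with_trace = TRUE)
  })
  records <- do.call(rbind, lapply(sessions, function(s) {
    trial_records(s$trace, s$schedule, s$timeline, s$participant_id,
                  rc$preprocess)
  }))
  if (keep_raw) list(records = records, sessions = sessions) else records
}

#' Run the full experiment end-to-end
#'
#' Simulates the cohort, screens nonresponders, and produces the complete
#' set of headline statistics: the selection-related EDA slope; win, loss,
#' near-win and near-loss outcome-EDA slopes with their two paired
#' contrasts; the four selection-outcome slope correlations with two
#' Williams tests; the four luck-rating slopes with two contrasts; and the
#' betting-behaviour summary. EDA slope fits also carry an
#' attenuation-corrected estimate `b_amp = b / kappa` on the amplitude
#' scale of the generative model.
#'
#' @param rc A [run_config()].
#' @param out_dir Optional directory: writes per-participant events.tsv and
#'   physio files (trace mode), the trial table, a JSON results file and a
#'   text report.
#' @return An object of class `eda_experiment`.
#' @export
run_experiment <- function(rc, out_dir = NULL) {
  stopifnot(inherits(rc, "run_config"))
  raw <- NULL
  if (rc$mode == "trace" && !is.null(out_dir)) {
    sim <- simulate_cohort(rc, keep_raw = TRUE)
    records <- sim$records
    raw <- sim$sessions
  } else {
    records <- simulate_cohort(rc)
  }
  screening <- screen_nonresponders(records, rc$preprocess)
  kept <- records[records$participant_id %in% screening$included, ]
  res <- analyze_records(kept, rc)
  res$screening <- screening
  res$config <- rc
  res$records <- kept
  class(res) <- "eda_experiment"
  if (!is.null(out_dir)) {
    write_experiment(res, raw, out_dir)
  }
  res
}

# Degenerate cohorts (too few participants or too little magnitude
# variation) skip the affected statistic with a warning instead of
# aborting the run.
safe_stat <- function(expr, label) {
  tryCatch(expr, error = function(e) {
    warning(sprintf("%s skipped: %s", label, conditionMessage(e)),
            call. = FALSE)
    NULL
  })
}

#' Run the full inference stage on a trial-record table
#'
#' All statistics computed from an (already preprocessed and screened)
#' trial-record table: the five EDA slope fits, the four luck-rating slope
#' fits, paired slope contrasts, selection-outcome slope-profile
#' correlations with their Williams tests, and the betting-behaviour
#' summary. Statistics whose preconditions fail on degenerate cohorts are
#' skipped with a warning rather than aborting.
#'
#' @param records A trial-record table (see [trial_records()]).
#' @param rc A [run_config()] supplying the preprocessing and kernel
#'   parameters used for the attenuation correction.
#' @return A list with `fits`, `luck_fits`, `contrasts`, `correlations`,
#'   `williams`, `behavior` and `kappa`.
#' @export
analyze_records <- function(records, rc) {
  kappa <- kernel_bin_attenuation(rc$amplitude, rc$preprocess)
  fit_eda <- function(conds, response = "outcome_eda",
                      predictor = "magnitude") {
    f <- fit_magnitude_slope(records, response, predictor, conds)
    f$b_amp <- f$b / kappa
    f$se_amp <- f$se / kappa
    f
  }
  fits <- list(
    selection = fit_eda(NULL, "selection_eda", "bet"),
    win = fit_eda("win"), loss = fit_eda("loss"),
    near_win = fit_eda("near_win"), near_loss = fit_eda("near_loss")
  )
  fit_luck <- function(cc) {
    safe_stat(fit_magnitude_slope(records, "luck_rating",
                                  "magnitude_signed", cc),
              sprintf("luck slope (%s)", cc))
  }
  luck_fits <- list(win = fit_luck("win"), loss = fit_luck("loss"),
                    near_win = fit_luck("near_win"),
                    near_loss = fit_luck("near_loss"))
  contrasts <- list(
    eda_loss_vs_win = safe_stat(
      paired_slope_test(fits$loss$participant_slopes,
                        fits$win$participant_slopes),
      "loss-vs-win slope contrast"),
    eda_nearloss_vs_nearwin = safe_stat(
      paired_slope_test(fits$near_loss$participant_slopes,
                        fits$near_win$participant_slopes),
      "near-loss-vs-near-win slope contrast"),
    luck_win_vs_loss = safe_stat(
      paired_slope_test(luck_fits$win$participant_slopes,
                        luck_fits$loss$participant_slopes),
      "luck win-vs-loss contrast"),
    luck_nearwin_vs_nearloss = safe_stat(
      paired_slope_test(luck_fits$near_win$participant_slopes,
                        luck_fits$near_loss$participant_slopes),
      "luck near contrast")
  )
  correlations <- list(
    sel_win = safe_stat(correlate_slope_profiles(fits$selection, fits$win),
                        "selection-win correlation"),
    sel_loss = safe_stat(correlate_slope_profiles(fits$selection, fits$loss),
                         "selection-loss correlation"),
    sel_near_win = safe_stat(
      correlate_slope_profiles(fits$selection, fits$near_win),
      "selection-near-win correlation"),
    sel_near_loss = safe_stat(
      correlate_slope_profiles(fits$selection, fits$near_loss),
      "selection-near-loss correlation"),
    win_loss = safe_stat(correlate_slope_profiles(fits$win, fits$loss),
                         "win-loss correlation"),
    nearwin_nearloss = safe_stat(
      correlate_slope_profiles(fits$near_win, fits$near_loss),
      "near-win-near-loss correlation")
  )
  williams <- list(
    obtained = safe_stat(
      williams_test(correlations$sel_loss$r, correlations$sel_win$r,
                    correlations$win_loss$r, correlations$sel_loss$n),
      "Williams test (obtained outcomes)"),
    near = safe_stat(
      williams_test(correlations$sel_near_loss$r,
                    correlations$sel_near_win$r,
                    correlations$nearwin_nearloss$r,
                    correlations$sel_near_loss$n),
      "Williams test (near outcomes)")
  )
  list(fits = fits, luck_fits = luck_fits, contrasts = contrasts,
       correlations = correlations, williams = williams,
       behavior = behavior_summary(records), kappa = kappa)
}

write_experiment <- function(res, raw, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(raw)) {
    for (s in raw) {
      write_events_tsv(s$schedule, s$timeline,
                       file.path(out_dir,
                                 paste0(s$participant_id, "_events.tsv")))
      write_physio(s$trace,
                   file.path(out_dir,
                             paste0(s$participant_id, "_physio.tsv.gz")),
                   participant_id = s$participant_id)
    }
  }
  write.table(res$records, file.path(out_dir, "trial_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(experiment_results_list(res),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format(res), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

# Flatten an eda_experiment into plain lists for JSON serialization.
experiment_results_list <- function(x) {
  sf <- function(f) list(b = f$b, se = f$se, t = f$t, df = f$df, p = f$p,
                         b_amp = f$b_amp, n_obs = f$n_obs,
                         n_participants = f$n_participants,
                         method = f$method)
  tr <- function(z) list(t = z$statistic, df = z$df, p = z$p,
                         estimate = z$estimate)
  wt <- function(w) list(t = w$statistic, df = w$df, p = w$p,
                         r12 = w$r12, r13 = w$r13, r23 = w$r23)
  opt <- function(z, f) if (is.null(z)) NULL else f(z)
  list(
    eda_slopes = lapply(x$fits, sf),
    luck_slopes = lapply(x$luck_fits, opt, f = sf),
    contrasts = lapply(x$contrasts, opt, f = tr),
    correlations = lapply(x$correlations, opt,
                          f = function(cc) list(r = cc$r, n = cc$n)),
    williams = lapply(x$williams, opt, f = wt),
    behavior = list(mean_bet = x$behavior$mean_bet,
                    post_win_change = x$behavior$post_win_change,
                    post_loss_change = x$behavior$post_loss_change,
                    total_winnings_gbp = x$behavior$total_winnings_gbp,
                    tests = lapply(x$behavior$tests,
                                   function(z) if (is.null(z)) NULL else tr(z))),
    n_excluded = length(x$screening$excluded),
    kappa = x$kappa
  )
}

#' @export
format.eda_experiment <- function(x, ...) {
  f <- x$fits; lf <- x$luck_fits
  line_fit <- function(lbl, ft) {
    if (is.null(ft)) return(sprintf("  %-28s (skipped)", lbl))
    sprintf("  %-28s b = %10.4g  SE = %9.3g  t = %6.2f  p = %.3g",
            lbl, ft$b, ft$se, ft$t, ft$p)
  }
  line_t <- function(lbl, z) {
    if (is.null(z)) return(sprintf("  %-28s (skipped)", lbl))
    sprintf("  %-28s t(%d) = %6.3f  p = %.3g", lbl, z$df, z$statistic, z$p)
  }
  rv <- function(cc) if (is.null(cc)) NA_real_ else cc$r
  wline <- function(lbl, a, b, w) {
    if (is.null(w)) {
      sprintf("  r(sel, %s) = %.3f; r(sel, %s) = %.3f; Williams test skipped",
              lbl[1], rv(a), lbl[2], rv(b))
    } else {
      sprintf("  r(sel, %s) = %.3f; r(sel, %s) = %.3f; Williams t(%d) = %.3f, p = %.3g",
              lbl[1], rv(a), lbl[2], rv(b), w$df, w$statistic, w$p)
    }
  }
  c(sprintf("Wheel-of-fortune EDA analysis (%d participants analysed, %d excluded)",
            f$selection$n_participants, length(x$screening$excluded)),
    "Behaviour:",
    sprintf("  mean bet %.1f p; post-win change %.2f p; post-loss change %.2f p; winnings GBP %.2f",
            x$behavior$mean_bet, x$behavior$post_win_change,
            x$behavior$post_loss_change, x$behavior$total_winnings_gbp),
    "Selection-related EDA:",
    line_fit("EDA ~ bet", f$selection),
    "Outcome-related EDA:",
    line_fit("win magnitude", f$win),
    line_fit("loss magnitude", f$loss),
    line_t("loss vs win slopes", x$contrasts$eda_loss_vs_win),
    line_fit("near-win magnitude", f$near_win),
    line_fit("near-loss magnitude", f$near_loss),
    line_t("near-loss vs near-win", x$contrasts$eda_nearloss_vs_nearwin),
    "Selection-outcome slope correlations:",
    wline(c("win", "loss"), x$correlations$sel_win, x$correlations$sel_loss,
          x$williams$obtained),
    wline(c("near-win", "near-loss"), x$correlations$sel_near_win,
          x$correlations$sel_near_loss, x$williams$near),
    "Luck ratings (signed magnitude):",
    line_fit("win magnitude", lf$win),
    line_fit("loss magnitude", lf$loss),
    line_t("win vs loss slopes", x$contrasts$luck_win_vs_loss),
    line_fit("near-win magnitude", lf$near_win),
    line_fit("near-loss magnitude", lf$near_loss),
    line_t("near-win vs near-loss", x$contrasts$luck_nearwin_vs_nearloss))
}

#' @export
print.eda_experiment <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

# Fast within-participant (demeaned) pooled OLS slope; equals the mixed
# model's fixed slope on balanced designs and is used in large replicate
# studies where refitting REML per replicate would dominate runtime.
within_participant_slope <- function(records, response, predictor,
                                     conditions = NULL) {
  d <- records[records$included, ]
  if (!is.null(conditions)) d <- d[d$condition %in% conditions, ]
  g <- factor(d$participant_id)
  x <- d[[predictor]]; y <- d[[response]]
  s <- rowsum(cbind(n = 1, x = x, y = y, xx = x * x, xy = x * y), g)
  sxx <- sum(s[, "xx"] - s[, "x"]^2 / s[, "n"])
  sxy <- sum(s[, "xy"] - s[, "x"] * s[, "y"] / s[, "n"])
  sxy / sxx
}

#' Replicate-based parameter recovery and test calibration
#'
#' Repeats cohort simulation over derived seeds and, per replicate,
#' re-estimates the five generative EDA slopes and runs the two paired
#' slope contrasts. Estimates are mapped to amplitude scale with the
#' closed-form kernel attenuation factor before comparison with the
#' generative values. With `mixed = FALSE` the slopes come from the
#' within-participant pooled OLS estimator instead of REML (fast path for
#' large calibration runs; identical in expectation on this design).
#'
#' @param rc A [run_config()] (summary mode is used regardless of
#'   `rc$mode`; see [run_config()]).
#' @param n_replicates Number of replicate cohorts (>= 2).
#' @param seed Master seed for the study (defaults to the config's).
#' @param mixed Use the REML mixed-model estimator per replicate.
#' @param alpha Level for rejection-rate summaries.
#' @return An object of class `recovery_report`: `parameters` data frame
#'   (truth, mean estimate, bias, relative bias, RMSE, CI coverage),
#'   rejection rates for the two contrasts, and the loss > win ordering
#'   rate.
#' @export
recovery_study <- function(rc, n_replicates = 200, seed = rc$master_seed,
                           mixed = TRUE, alpha = 0.05) {
  if (n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  rep_seeds <- derive_seeds(seed + 1L, n_replicates)
  amp <- rc$amplitude
  truth <- c(selection = amp$selection_slope, win = amp$win_slope,
             loss = amp$loss_slope, near_win = amp$near_win_slope,
             near_loss = amp$near_loss_slope)
  kappa <- kernel_bin_attenuation(amp, rc$preprocess)
  est <- matrix(NA_real_, n_replicates, 5,
                dimnames = list(NULL, names(truth)))
  cover <- matrix(NA, n_replicates, 5, dimnames = list(NULL, names(truth)))
  rej_lw <- rej_nlnw <- order_lw <- logical(n_replicates)
  specs <- list(selection = list("selection_eda", "bet", NULL),
                win = list("outcome_eda", "magnitude", "win"),
                loss = list("outcome_eda", "magnitude", "loss"),
                near_win = list("outcome_eda", "magnitude", "near_win"),
                near_loss = list("outcome_eda", "magnitude", "near_loss"))
  for (r in seq_len(n_replicates)) {
    rec <- simulate_cohort_records(rc, rep_seeds[r])
    if (mixed) {
      for (j in seq_along(specs)) {
        sp <- specs[[j]]
        ft <- fit_magnitude_slope(rec, sp[[1]], sp[[2]], sp[[3]])
        est[r, j] <- ft$b / kappa
        cover[r, j] <- abs(ft$b - kappa * truth[j]) <= 1.96 * ft$se
      }
    } else {
      for (j in seq_along(specs)) {
        sp <- specs[[j]]
        est[r, j] <- within_participant_slope(rec, sp[[1]], sp[[2]],
                                              sp[[3]]) / kappa
      }
    }
    sl <- lapply(c(win = "win", loss = "loss", near_win = "near_win",
                   near_loss = "near_loss"), function(cc) {
      per_participant_slopes(rec[rec$included & rec$condition == cc, ],
                             "outcome_eda", "magnitude")
    })
    t_lw <- paired_slope_test(sl$loss, sl$win)
    t_nn <- paired_slope_test(sl$near_loss, sl$near_win)
    rej_lw[r] <- t_lw$p < alpha
    rej_nlnw[r] <- t_nn$p < alpha
    order_lw[r] <- est[r, "loss"] > est[r, "win"]
  }
  mean_est <- colMeans(est)
  bias <- mean_est - truth
  params <- data.frame(
    parameter = names(truth), truth = as.numeric(truth),
    mean_estimate = as.numeric(mean_est), bias = as.numeric(bias),
    relative_bias = as.numeric(bias / truth),
    rmse = as.numeric(sqrt(colMeans(sweep(est, 2, truth)^2))),
    ci_coverage = as.numeric(colMeans(cover)),
    stringsAsFactors = FALSE
  )
  structure(list(parameters = params,
                 rejection_loss_vs_win = mean(rej_lw),
                 rejection_nearloss_vs_nearwin = mean(rej_nlnw),
                 ordering_loss_gt_win = mean(order_lw),
                 n_replicates = n_replicates, alpha = alpha,
                 kappa = kappa, mixed = mixed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates (%s estimator)\n",
              x$n_replicates,
              if (x$mixed) "REML mixed" else "within-participant OLS"))
  print(x$parameters, row.names = FALSE, digits = 4)
  cat(sprintf("  loss>win rejection %.3f | near rejection %.3f | loss>win ordering %.3f\n",
              x$rejection_loss_vs_win, x$rejection_nearloss_vs_nearwin,
              x$ordering_loss_gt_win))
  invisible(x)
}
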