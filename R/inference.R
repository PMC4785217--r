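#' Fit a random-intercept magnitude slope
#'
#' Fits `response ~ predictor + (1 | participant_id)` by restricted maximum
#' likelihood on the included trials of the selected conditions, returning
#' the fixed-effect slope with its Satterthwaite-approximated t test, plus
#' per-participant ordinary-least-squares slopes for downstream paired
#' contrasts and slope-profile correlations. If the random-intercept
#' variance is estimated as zero (singular fit) the function falls back to
#' pooled ordinary least squares and flags it.
#'
#' @param records A trial-record table (see [trial_records()]).
#' @param response,predictor Column names, e.g. `"outcome_eda"` and
#'   `"magnitude"`.
#' @param conditions Conditions to keep (default: all included trials).
#' @param include_only Drop trials flagged `included = FALSE` (fillers).
#' @return An object of class `slope_fit` with elements `b`, `se`, `t`,
#'   `df`, `p`, `intercept`, `participant_slopes`, `n_obs`,
#'   `n_participants`, `method`.
#' @export
fit_magnitude_slope <- function(records, response, predictor,
                                conditions = NULL, include_only = TRUE) {
  d <- records
  if (include_only && "included" %in% names(d)) d <- d[d$included, ]
  if (!is.null(conditions)) d <- d[d$condition %in% conditions, ]
  d <- d[stats::complete.cases(d[, c(response, predictor, "participant_id")]), ]
  if (length(unique(d$participant_id)) < 2L)
    stop("need at least 2 participants to fit a mixed model", call. = FALSE)
  if (length(unique(d[[predictor]])) < 2L)
    stop("predictor has fewer than 2 distinct values", call. = FALSE)
  dat <- data.frame(y = d[[response]], x = d[[predictor]],
                    participant_id = factor(d$participant_id))
  fml <- y ~ x + (1 | participant_id)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(fml, data = dat, REML = TRUE)),
    error = function(e) NULL
  )
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    ols <- lm(y ~ x, data = dat)
    cf <- summary(ols)$coefficients
    out <- list(b = cf["x", "Estimate"], se = cf["x", "Std. Error"],
                t = cf["x", "t value"], df = ols$df.residual,
                p = cf["x", "Pr(>|t|)"],
                intercept = cf["(Intercept)", "Estimate"],
                method = "pooled_ols")
  } else {
    cf <- coef(summary(fit))
    out <- list(b = cf["x", "Estimate"], se = cf["x", "Std. Error"],
                t = cf["x", "t value"], df = cf["x", "df"],
                p = cf["x", "Pr(>|t|)"],
                intercept = cf["(Intercept)", "Estimate"],
                method = "lmm_reml_satterthwaite")
  }
  out$participant_slopes <- per_participant_slopes(d, response, predictor)
  out$n_obs <- nrow(dat)
  out$n_participants <- nlevels(dat$participant_id)
  out$response <- response
  out$predictor <- predictor
  out$conditions <- conditions
  structure(out, class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> %s ~ %s%s [%s]\n  b = %.4g, SE = %.3g, t(%.1f) = %.3f, p = %.3g\n  %d obs, %d participants\n",
    x$response, x$predictor,
    if (is.null(x$conditions)) "" else
      paste0(" (", paste(x$conditions, collapse = "+"), ")"),
    x$method, x$b, x$se, x$df, x$t, x$p, x$n_obs, x$n_participants))
  invisible(x)
}

#' Per-participant ordinary-least-squares slopes
#'
#' Closed-form OLS slope of `response` on `predictor` within each
#' participant; `NA` for participants with fewer than two distinct
#' predictor values.
#'
#' @inheritParams fit_magnitude_slope
#' @return Named numeric vector of slopes.
#' @export
per_participant_slopes <- function(records, response, predictor) {
  g <- factor(records$participant_id)
  x <- records[[predictor]]
  y <- records[[response]]
  ok <- !is.na(x) & !is.na(y)
  g <- g[ok]; x <- x[ok]; y <- y[ok]
  s <- rowsum(cbind(n = 1, x = x, y = y, xx = x * x, xy = x * y),
              g, reorder = TRUE)
  sxx <- s[, "xx"] - s[, "x"]^2 / s[, "n"]
  sxy <- s[, "xy"] - s[, "x"] * s[, "y"] / s[, "n"]
  slope <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
  setNames(as.numeric(slope), rownames(s))
}

#' Paired t test on per-participant slopes
#'
#' Compares two slope vectors from the same participants (e.g. the loss
#' versus win EDA magnitude slopes) with a paired t test, `df = n - 1`.
#' Zero-variance differences are flagged degenerate and the p value is
#' reported as the smallest representable positive number (or 1 when the
#' two inputs are identical).
#'
#' @param slopes_a,slopes_b Named per-participant slope vectors over the
#'   same participant set.
#' @return An object of class `test_result`.
#' @export
paired_slope_test <- function(slopes_a, slopes_b) {
  if (is.null(names(slopes_a)) || is.null(names(slopes_b)) ||
      !setequal(names(slopes_a), names(slopes_b)))
    stop("slope vectors must be named over the same participant set",
         call. = FALSE)
  slopes_b <- slopes_b[names(slopes_a)]
  ok <- !is.na(slopes_a) & !is.na(slopes_b)
  d <- slopes_a[ok] - slopes_b[ok]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  m <- mean(d); s <- sd(d)
  if (s < .Machine$double.eps * max(1, abs(m))) {
    degenerate <- TRUE
    if (abs(m) < .Machine$double.eps) {
      t <- 0; p <- 1
    } else {
      t <- sign(m) * Inf; p <- .Machine$double.xmin
    }
  } else {
    degenerate <- FALSE
    t <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t), n - 1)
  }
  structure(list(statistic = t, df = n - 1L, p = p, estimate = m,
                 kind = "paired_t", n = n, degenerate = degenerate),
            class = "test_result")
}

#' One-sample t test
#'
#' Standard one-sample t test of `values` against `mu0`, `df = n - 1`,
#' with the same degenerate-variance flagging as [paired_slope_test()].
#'
#' @param values Numeric vector.
#' @param mu0 Null value.
#' @return An object of class `test_result`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values) - mu0
  s <- sd(values)
  if (s < .Machine$double.eps * max(1, abs(m))) {
    degenerate <- TRUE
    if (abs(m) < .Machine$double.eps) {
      t <- 0; p <- 1
    } else {
      t <- sign(m) * Inf; p <- .Machine$double.xmin
    }
  } else {
    degenerate <- FALSE
    t <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t), n - 1)
  }
  structure(list(statistic = t, df = n - 1L, p = p, estimate = m + mu0,
                 kind = "one_sample_t", n = n, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: t(%d) = %.3f, p = %.3g, estimate = %.4g%s\n",
              x$kind, x$df, x$statistic, x$p, x$estimate,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Williams test for two dependent correlations sharing a variable
#'
#' Tests whether `r12` and `r13` (two correlations sharing variable 1)
#' differ, given the correlation `r23` between variables 2 and 3, using
#' Steiger's modification of Williams's t2:
#' \deqn{t = (r_{12} - r_{13}) \sqrt{\frac{(n-1)(1+r_{23})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 +
#' 2 r_{12} r_{13} r_{23}}, \eqn{\bar r = (r_{12}+r_{13})/2} and
#' `df = n - 3`.
#'
#' @param r12,r13 The two dependent correlations being compared.
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (number of paired observations), at least 4.
#' @return An object of class `williams_test` with `statistic`, `df`, `p`
#'   and the input correlations.
#' @export
williams_test <- function(r12, r13, r23, n) {
  if (n < 4) stop("Williams test needs n >= 4", call. = FALSE)
  rs <- c(r12 = r12, r13 = r13, r23 = r23)
  if (any(abs(rs) >= 1))
    stop("correlations must lie strictly within (-1, 1)", call. = FALSE)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-10)
    stop(sprintf(
      "correlation triple is not positive semidefinite (|R| = %.3g)", detR),
      call. = FALSE)
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  structure(list(statistic = t, df = df, p = 2 * pt(-abs(t), df),
                 r12 = r12, r13 = r13, r23 = r23, n = n),
            class = "williams_test")
}

#' @export
print.williams_test <- function(x, ...) {
  cat(sprintf(
    "<williams_test> r12 = %.3f vs r13 = %.3f (r23 = %.3f, n = %d): t(%d) = %.3f, p = %.3g\n",
    x$r12, x$r13, x$r23, x$n, x$df, x$statistic, x$p))
  invisible(x)
}

#' Monte-Carlo type-I calibration of the Williams test
#'
#' Draws replicate samples of size `n` from a trivariate normal whose
#' population correlations satisfy the null `rho12 = rho13`, applies
#' [williams_test()] to the sample correlations, and returns the rejection
#' rate at level `alpha`.
#'
#' @param n Per-replicate sample size.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param rho Common population value of `rho12 = rho13`.
#' @param rho23 Population correlation between variables 2 and 3.
#' @param alpha Nominal level.
#' @param seed Optional integer seed.
#' @return A list with the rejection `rate`, its binomial `se`, `n_reps`.
#' @export
williams_calibration <- function(n = 50, n_reps = 5000, rho = 0.5,
                                 rho23 = 0.3, alpha = 0.05, seed = NULL) {
  maybe_seed(seed)
  sigma <- matrix(c(1, rho, rho,
                    rho, 1, rho23,
                    rho, rho23, 1), 3, 3)
  L <- chol(sigma)
  rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    x <- matrix(rnorm(n * 3), n, 3) %*% L
    r <- cor(x)
    w <- williams_test(r[1, 2], r[1, 3], r[2, 3], n)
    rej[i] <- w$p < alpha
  }
  rate <- mean(rej)
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_reps), n_reps = n_reps)
}

#' Correlate two per-participant slope profiles
#'
#' Pearson correlation between the per-participant OLS slopes of two fits
#' over their shared participants.
#'
#' @param fit_a,fit_b Objects of class `slope_fit` (or named slope vectors).
#' @return An object of class `slope_correlation` with `r` and `n`.
#' @export
correlate_slope_profiles <- function(fit_a, fit_b) {
  a <- if (inherits(fit_a, "slope_fit")) fit_a$participant_slopes else fit_a
  b <- if (inherits(fit_b, "slope_fit")) fit_b$participant_slopes else fit_b
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 4L) stop("need at least 4 shared participants", call. = FALSE)
  constant <- sd(a) < 1e-15 || sd(b) < 1e-15
  r <- if (constant) NA_real_ else cor(a, b)
  structure(list(r = r, n = n, constant = constant,
                 participants = names(a)),
            class = "slope_correlation")
}

#' @export
print.slope_correlation <- function(x, ...) {
  cat(sprintf("<slope_correlation> r = %.3f (n = %d)%s\n", x$r, x$n,
              if (isTRUE(x$constant)) " [constant input]" else ""))
  invisible(x)
}

#' Betting-behaviour summary
#'
#' Per participant: mean bet, mean bet change following wins and following
#' losses, and total winnings; plus group-level one-sample t tests against
#' zero for the change scores and total winnings (in pounds).
#'
#' @param records A trial-record table in session order (must contain
#'   `participant_id`, `trial_index`, `condition`, `bet`, `outcome_pence`).
#' @return An object of class `behavior_summary` with a per-participant
#'   data frame and the group tests.
#' @export
behavior_summary <- function(records) {
  need <- c("participant_id", "trial_index", "condition", "bet",
            "outcome_pence")
  if (!all(need %in% names(records)))
    stop("records are missing behaviour columns", call. = FALSE)
  per <- lapply(split(records, records$participant_id), function(d) {
    d <- d[order(d$trial_index), ]
    n <- nrow(d)
    chg <- if (n > 1) d$bet[-1] - d$bet[-n] else numeric(0)
    prev <- d$condition[-n]
    data.frame(
      participant_id = d$participant_id[1],
      mean_bet = mean(d$bet),
      post_win_change = if (any(prev == "win"))
        mean(chg[prev == "win"]) else NA_real_,
      post_loss_change = if (any(prev == "loss"))
        mean(chg[prev == "loss"]) else NA_real_,
      total_winnings_gbp = sum(d$outcome_pence) / 100,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  tests <- list(
    post_win = if (sum(!is.na(per$post_win_change)) >= 2)
      one_sample_t(per$post_win_change) else NULL,
    post_loss = if (sum(!is.na(per$post_loss_change)) >= 2)
      one_sample_t(per$post_loss_change) else NULL,
    winnings = if (nrow(per) >= 2)
      one_sample_t(per$total_winnings_gbp) else NULL
  )
  structure(list(participants = per,
                 mean_bet = mean(per$mean_bet),
                 post_win_change = mean(per$post_win_change, na.rm = TRUE),
                 post_loss_change = mean(per$post_loss_change, na.rm = TRUE),
                 total_winnings_gbp = mean(per$total_winnings_gbp),
                 tests = tests),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    "<behavior_summary> mean bet %.1f p; post-win change %.2f p; post-loss change %.2f p; winnings GBP %.2f\n",
    x$mean_bet, x$post_win_change, x$post_loss_change, x$total_winnings_gbp))
  invisible(x)
}
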