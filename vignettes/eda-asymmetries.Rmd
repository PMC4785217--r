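---
title: "Simulating and testing electrodermal asymmetries in a wheel-of-fortune task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and testing electrodermal asymmetries in a wheel-of-fortune task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

"Losses loom larger than gains" is the central asymmetry of prospect
theory. One physiological expression of it: skin-conductance (EDA)
responses to monetary outcomes in a gambling task scale with outcome
magnitude, and the magnitude *slope* is steeper for losses than for
equally sized wins — and, more subtly, steeper for narrowly missed losses
(near-losses) than for narrowly missed wins (near-wins), even though both
near outcomes pay nothing. Because no recordings from such a study are
publicly deposited, everything downstream of the electrodes must be
validated against synthetic data with known ground truth. `edawheel`
therefore implements the complete chain — task simulation, conductance
synthesis, trial-locked feature extraction, mixed-model slope estimation,
dependent-correlation testing — as tested, reusable code, and verifies by
parameter recovery that the chain returns the asymmetries it was fed.

## The task model

Each session has 76 trials: 19 wins, 19 losses, 10 near-wins, 10
near-losses and 18 fillers, in a fully shuffled order. The wheel is
modelled as four 90° segments (gain and loss opposite one another,
separated by two null segments); the spinner's stop is summarized by its
angular offset from the nearest segment boundary. Near outcomes stop
within 1.8° of the win or loss boundary; fillers stop at least 20° from
any boundary, i.e. near the centre of a null segment, so that "a null
outcome close to neither a win nor a loss" is well defined. The segment
layout is a modelling choice — only the 1.8° bound is dictated by the task
description — and fixed win/loss segment positions are assumed.

Bets lie on a 10–90 pence grid in 10 p steps, anchored at 50 p, and pay
±10× the bet on win/loss trials. A trial runs: self-paced bet choice
(log-normal latency, mean 2.91 s, SD 2.0 s, floored at 0.2 s), a spin of
5.3–6.9 s (uniform), a 1 s outcome phase plus 1 s numeric display, a
self-paced luck rating (log-normal, mean 2.44 s, SD 1.75 s), and a 10 s
intertrial interval (ITI). Sessions open with a 300 s rest recording, so
the first trial has a pre-choice baseline window like every other trial.

The betting agent captures the asymmetric gambler's fallacy: after a win
the next bet shifts by −5.77 p, after a loss by +3.40 p, plus Gaussian
transition noise (SD 9 p, matching the reported change-score SDs of
8.69/9.76 p), snapped to the grid (exact midpoints snap to the lower
level) and clipped to its range. Snapping and clipping attenuate the
*measured* mean change scores relative to the generative shifts — a bet of
90 p cannot rise — so recovery tests compare the pipeline's estimates
against an independent Monte-Carlo oracle of the same walk rather than
against the raw shift parameters. Because condition counts are fixed
per session, outcomes are negatively autocorrelated, and an agent that
bets down after wins tends to bet low when losses are due: the asymmetric
policy yields positive expected winnings with no informational advantage.

## The conductance model

Traces are built in log10 space and exponentiated to microsiemens:

    log10 EDA(t) = tonic_i + drift(t) + measurement noise
                   + sum over events of a_event * h(t - onset - 1.0 s)

with `h` the bi-exponential unit-peak kernel `c·(e^(−t/4.0) − e^(−t/0.75))`
(rise 0.75 s, decay 4.0 s, onset latency 1.0 s — typical electrodermal
values), drift a slow sinusoid (amplitude 0.05 log units, period 120 s,
random phase) and white measurement noise (SD 0.005 log units). Building
the signal additively in log space means the analysis-side log transform
makes every modelled quantity exactly linear in bet and magnitude, which
is what the downstream linear models assume.

Event amplitudes carry the ground truth:

    a_event = gain_i * (intercept + slope * magnitude + u_i + e_trial),  floored at 0

with condition slopes (log10 µS per pence) set to the empirical estimates
the pipeline is designed to recover — selection 6.30×10⁻⁴ (per pence of
bet), win 2.625×10⁻⁵, loss 8.35×10⁻⁵, near-win 6.34×10⁻⁵, near-loss
7.23×10⁻⁵ — phase intercepts of 0.02, a participant offset `u_i`
(SD 0.005) and trial noise (SD 0.005). `gain_i` is a log-normal
responsiveness factor (log-SD 0.6, mean fixed at 1): it induces the
between-participant slope variation that makes selection- and
outcome-slope profiles correlate across people, the structure the Williams
tests operate on. Noise terms sit *inside* the gain bracket (variability
scales with responsiveness) and are kept small relative to the intercept
so the floor at zero almost never binds; a floored amplitude would
otherwise bend the very linearity the estimators assume. The flip side is
that simulated t statistics run larger than human data, which carry
residual variability this generator deliberately omits (habituation,
respiration and movement artifacts, electrode drift beyond the sinusoid).

## The reduction

Traces are decimated to 100 Hz (zero-phase FIR low-pass at 80% of the
target Nyquist, reflection-padded), log10-transformed with a 10⁻³ µS floor
(far below physiological range; the log base is a convention choice), and
summarized per trial as the maximum of (bin mean − baseline) over bins
2–4 of four half-open 2 s bins from the choice onset and from the outcome
onset. The baseline is the mean over the last 2 s of the preceding ITI —
operationally the 2 s before the choice onset, which for trial 1 falls in
the rest-period tail. Three conventions are fixed here because the verbal
description underdetermines them: the baseline statistic is the *mean*;
"maximum change" is the *signed* maximum (EDA responses of interest are
rises, and the signed form keeps the summary linear in amplitude); the
same preceding-ITI baseline serves both the choice-locked and
outcome-locked summaries. Participants whose outcome summaries have an
across-trial SD below 10⁻⁴ log units are screened out as electrodermal
nonresponders (the qualitative "no phasic changes" criterion made
operational).

Averaging the kernel over 2 s bins attenuates a response of amplitude `a`
to `κ·a`, where `κ` (≈ 0.943 at the defaults) has a closed form from the
kernel integral. `kernel_bin_attenuation()` computes it, and recovery
studies divide summary-scale slope estimates by `κ` so they are compared
with the generative amplitudes on a common scale.

## Inference

Slopes are estimated with random-intercept models,
`EDA ~ magnitude + (1 | participant)`, by REML via `lme4`, with
Satterthwaite p values via `lmerTest`; a fit with zero between-participant
variance falls back to pooled OLS and is flagged. Magnitudes enter in
pence, uncentred (bets 10–90, outcomes 100–900), matching the scale of
the default coefficients. Slope *contrasts* use a paired t test over
per-participant OLS slopes — the verbal description ("compared the slopes
for each participant") fits this reading better than an interaction term
in a combined model, though both are computable from the returned
per-participant slopes. Profile correlations are Pearson correlations of
per-participant slope vectors, and two dependent correlations sharing the
selection slope are compared with Steiger's modification of Williams's
t2 (df = n − 3), the third correlation being computed from the data. No
multiple-testing correction is applied anywhere, matching the analysis
being emulated.

Luck ratings (1–9 scale, default 5) use the same machinery with one
twist: magnitudes enter *signed* (losses and near-losses negative). The
published coefficient pattern for luck — positive for wins ("luckier"),
positive for losses ("unluckier"), negative for near-wins, negative for
near-losses — is mutually consistent only under signed coding, so that is
the default, with the four printed coefficients (2.56×10⁻³, 2.29×10⁻³,
−1.34×10⁻³, −1.21×10⁻³) used verbatim as generative defaults; an
`unsigned` switch is provided for the alternative reading.

## Validation strategy and problem sizes

Two generation paths share all behavioural code. The *trace* path runs
the full chain (synthesis → decimation → log → baseline → binning); the
*summary* path emits `κ·amplitude + noise` directly, with a summary-noise
SD of 0.025 log units standing in for the baseline/drift variability a
real trace adds. The two agree trial-for-trial (within 10⁻³) when noise
sources are off and events are isolated. Replicate studies use the
summary path: 200 replicate 50-participant cohorts recover all five
generative slopes with well under 5% relative bias and reproduce the
loss > win ordering in essentially every replicate; 5,000-replicate runs
under an equal-slope generative model hold the paired test at its nominal
5% level, and 5,000 trivariate-normal replicates do the same for the
Williams test. These sizes keep the full suite and the acceptance script
in the minutes range while leaving Monte-Carlo error well below the
tolerances being checked.

The trace path is *not* bias-free: the choice-phase response decays into
the outcome window, and because outcome magnitude is exactly 10× the bet,
that leakage adds a small magnitude-correlated component to outcome
summaries (visible as a few-percent inflation of the win slope in
trace-mode cohorts). It affects win and loss conditions symmetrically, so
ordering and contrast conclusions are unaffected; it is one reason the
recovery criteria are evaluated on the summary path, and it mirrors a
real property of slow electrodermal signals in this design.

## Known limitations

- The random-intercept-only model (deliberately matching the analysis
  being emulated) ignores the between-participant slope variation the
  generator creates, so its fixed-slope standard errors are
  anticonservative: nominal 95% CIs cover the generative value well below
  95% in recovery reports. The paired contrasts, built directly on
  per-participant slopes, do not inherit this problem.
- At the default effect sizes and noise, the near-loss vs near-win
  contrast (10 trials per condition, generative difference 0.89×10⁻⁵) has
  low power per cohort; the pipeline reports it but a single simulated
  cohort should not be expected to reject.
- The generator does not model habituation, respiration artifacts, or
  nonstationary electrode drift; passing recovery here shows the
  *pipeline* is faithful, not that real recordings are this clean.
- Luck ratings are integer-rounded and clipped, so their slopes are only
  approximately linear near the scale ends; at the defaults the rounding
  is dithered by the rating noise and the induced bias is negligible.
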