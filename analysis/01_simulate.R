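#!/usr/bin/env Rscript

# Stage 1 — simulate the cohort.
#
# Generates the default study: 50 participants, each playing one 76-trial
# wheel-of-fortune session (19 wins, 19 losses, 10 near-wins, 10
# near-losses, 18 fillers; bets on the 10-90 p grid; +/-10x payoffs), with
# a betting agent that bets down after wins more than it bets up after
# losses, trial-wise luck ratings, and a continuous 100 Hz skin-conductance
# trace per participant whose phasic response amplitudes scale linearly
# with bet and outcome magnitude at the condition-specific generative
# slopes (loss > win, near-loss > near-win).
#
# Raw session files (BIDS-style events.tsv + gzipped physio traces) go to
# scratch/cohort/ (large, regenerable); nothing downstream needs anything
# else from this stage.

suppressMessages(library(edawheel))

master_seed <- 20151214
out_raw <- "scratch/cohort"
dir.create(out_raw, recursive = TRUE, showWarnings = FALSE)

rc <- run_config(master_seed = master_seed, mode = "trace")
message("Simulating ", rc$n_participants, " participants (seed ",
        master_seed, ") ...")
sim <- simulate_cohort(rc, keep_raw = TRUE)

for (s in sim$sessions) {
  write_events_tsv(s$schedule, s$timeline,
                   file.path(out_raw, paste0(s$participant_id,
                                             "_events.tsv")))
  write_physio(s$trace,
               file.path(out_raw, paste0(s$participant_id,
                                         "_physio.tsv.gz")),
               participant_id = s$participant_id, seed = master_seed)
  write_behavior_tsv(s$schedule,
                     file.path(out_raw, paste0(s$participant_id,
                                               "_behavior.tsv")))
}

tab <- table(sim$sessions[[1]]$schedule$condition)
message("Session design: ", paste(names(tab), tab, sep = "=",
                                  collapse = ", "))
message("Wrote ", 3 * length(sim$sessions), " raw files to ", out_raw)
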