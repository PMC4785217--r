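Package: edawheel
Title: Electrodermal Reactivity to Wins, Losses, and Near Misses in a
    Wheel-of-Fortune Gambling Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for trial-locked electrodermal
    activity (EDA) in a wheel-of-fortune gambling task. Generates task
    schedules with wins, losses, near-wins, near-losses and filler trials,
    synthesizes skin-conductance traces with known ground-truth response
    amplitudes, reduces them to trial-wise summary measures (log transform,
    intertrial-interval baseline, 2-s binning, max-change summary), estimates
    condition-specific magnitude slopes with random-intercept mixed models,
    and tests loss/gain and near-loss/near-win asymmetries, including
    Williams tests of dependent correlations and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
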