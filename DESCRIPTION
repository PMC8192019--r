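Package: snplastr
Title: Sequentially Neuromodulated Plasticity in a Spiking Model of Reward Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hippocampal reward-based spatial navigation with a
    spiking place-cell-to-action-ring network whose feedforward synapses follow
    the sequentially neuromodulated plasticity (sn-Plast) rule: a symmetric
    spike-timing window whose sign is set by acetylcholine (immediate
    depression during exploration) and dopamine (retroactive potentiation at
    reward through a decaying eligibility trace). Provides the two-stage
    initial/reversal place-learning protocol, grid-search model fitting of
    per-subject learning curves by RMSE, parameter-recovery utilities,
    synthetic behavioural cohort generators, and trial-outcome statistics
    (fixed-effects logistic regression, days-to-criterion, rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    stats,
    utils,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
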