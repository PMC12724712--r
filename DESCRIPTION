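Package: mtspike
Title: Multi-Timescale Analysis of Brainstem Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the temporal organization of single-unit
    spike trains recorded from pain-modulatory brainstem neurons (ON-, OFF-,
    and NEUTRAL-cells of the rostral ventromedial medulla). Provides piecewise
    Bayesian change-point models of stimulus-evoked population spike counts
    with exponential/sigmoidal response and multi-timescale recovery phases,
    negative-log-marginal-likelihood period scans and latent Gaussian-process
    models of slow quasi-periodic ongoing firing with a generalized Poisson
    observation model, multitaper coherence between firing rate and heart rate
    with phase-randomized surrogate max-statistic family-wise inference, and
    animal-level permutation tests for group comparisons. Includes a synthetic
    cohort generator emulating the statistical structure of such recordings so
    that every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rjags,
    coda,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
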