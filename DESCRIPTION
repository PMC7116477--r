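Package: npdirect
Title: Non-Parametric Directionality and Granger Causality for Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Frequency-resolved directed functional connectivity for continuous
    multichannel neural recordings (LFP, EEG, MEG). Implements non-parametric
    directionality (NPD): the decomposition of magnitude-squared coherence into
    forward-lagged, reverse-lagged and instantaneous components via MMSE spectral
    pre-whitening and time-lag partitioning of the whitened cross-correlation;
    a conditioned (partialized) variant that removes the linear contribution of a
    reference channel; and non-parametric Granger causality (NPG) computed from
    Wilson spectral-matrix factorization, in pairwise and conditional multivariate
    forms. Includes a multivariate autoregressive (MVAR) simulator with an
    observation model for signal-to-noise and instantaneous-mixing confounds,
    phase-randomization surrogate statistics, confound-calibration sweeps with
    logistic summaries, and a directed-graph recovery benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
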