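Package: envhmm
Title: Transient Brain-State Dynamics of Band-Limited Power Envelopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of fast transient brain states in resting-state
    electrophysiological power envelopes. Provides a Gaussian-observation
    hidden Markov model with expectation-maximization fitting, restart
    selection and Viterbi decoding of mutually exclusive state visits;
    envelope preprocessing (Hilbert envelope extraction, moving-window
    downsampling, per-recording standardization, PCA whitening); state
    temporal statistics (mean life time, fractional occupancy, mean
    interval length, number of occurrences) and partial-correlation state
    maps; behavioural indices for motor sequence learning (global
    performance index, baseline, best motor performance, learning index,
    boost effect); a non-parametric statistical battery (paired Wilcoxon
    signed-rank, Spearman correlations, Bonferroni family corrections,
    bootstrap comparison of dependent correlations); and a synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
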