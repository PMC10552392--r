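Package: mmseeg
Title: Multivariate Multiscale Sample Entropy Analysis of Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multivariate multiscale sample entropy (mMSE) profiles of
    multichannel resting-state EEG over electrode sets corresponding to the seven
    canonical resting-state functional networks, reduces each 12-scale profile to
    four curve features (AUC, MaxSlope, AvgEnt, DiffEnt), and assesses them with
    segment-wise internal consistency (Cronbach's alpha) and mixed
    within/between-subject ANOVA with Greenhouse-Geisser correction. Includes a
    preprocessing cascade for raw recordings (resampling, band-pass filtering,
    SD-based bad-channel detection, staged amplitude-based epoch rejection,
    average referencing), minimal BrainVision and EDF readers/writers, and a
    surrogate-EEG cohort generator with controllable white/1-over-f/autoregressive
    mixture structure, cross-channel correlation, group contrasts and injectable
    artifacts, so the full pipeline is testable without real recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
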