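Package: cravereg
Title: Simulation and Analysis Pipeline for Craving-Regulation Task fMRI
Version: 0.1.0
Authors@R: person("cravereg", "developers", role = c("aut", "cre"),
    email = "cravereg@example.org")
Description: A tested re-implementation of a craving-regulation task fMRI
    analysis workflow: first-level general linear models with canonical
    HRF convolution, discrete-cosine high-pass filtering and AR(1)
    prewhitening; cross-cue searchlight multivariate pattern decoding
    with a linear support vector classifier and permutation-derived
    empirical chance maps; beta-series functional connectivity with the
    network-based statistic and link-wise FDR; permutation-based
    group-level family-wise-error correction; and repeated-measures
    ANOVA with Huynh-Feldt sphericity correction for behavioral craving
    ratings. A synthetic-data module generates experimental designs,
    BOLD volumes, phantom atlases, ratings and beta series with the
    statistical structure the analyses assume, so the whole pipeline is
    testable end-to-end without any data download. Includes a minimal
    NIfTI-1 reader/writer and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
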