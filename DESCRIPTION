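Package: sdrdecode
Title: Subject-Specific Decoding of Short-Duration Levodopa Response from
    Motor-Cortical Band Power
Version: 0.1.0
Authors@R:
    person("SDR", "Decode Maintainers", email = "maintainers@sdrdecode.org",
           role = c("aut", "cre"))
Description: Tools for analysing the short-duration levodopa response (SDR)
    in Parkinson's disease from resting-state source-space
    magnetoencephalography-like signals and MDS-UPDRS Part III motor
    ratings. Provides MDS-UPDRS motor-factor scoring (7 factors),
    spectral feature extraction (high-frequency epoch rejection,
    order-18 Butterworth lowpass, 5 s snippets with 50 percent overlap,
    Welch power spectra on a 0.5 Hz grid, band power in the 7-13, 13-20,
    20-30 and 35-45 Hz bands), per-subject linear soft-margin SVM
    decoding of medication state with unshuffled stratified 10-fold
    cross-validation, fold-averaged ROC curves and frequency-band
    weight profiles, one-dimensional Bayesian optimisation of the SVM
    box constraint, a nonparametric statistics battery (Wilcoxon
    signed-rank, Friedman, Benjamini-Hochberg, Spearman matrix,
    accuracy-versus-clinical-change regression), and a synthetic
    cohort generator that emulates the statistical structure these
    analyses assume so that every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
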