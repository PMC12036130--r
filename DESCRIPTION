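Package: fcea
Title: Network-Pair Enrichment Analysis of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens associations between ROI-pair functional connectivity and
    behavioral scores with mass-univariate linear regression, then summarizes the
    screening statistics at the functional network-pair level with three enrichment
    statistics (over-representation analysis, max-mean, and a GSEA-style running-sum
    score), assigning p-values by brain-wide-consistent subject-level permutation.
    Includes ROI time-series post-processing (framewise-displacement censoring,
    nuisance regression, band-pass filtering, Fisher-z connectivity), subject and
    parcellation quality control, hit extraction and anatomical classification,
    family-wise error calibration by min-p resampling, and a synthetic brain-behavior
    cohort generator with an optional planted network-pair coupling for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
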