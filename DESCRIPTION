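Package: pianos
Title: Platform-Independent, Normalization-Free Single-Sample Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies a single-sample prognostic risk classifier for
    expression cohorts. Each sample's gene expression profile is transformed
    into pathway enrichment scores with a rank-weighted single-sample running
    sum (ssGSEA), so that downstream computation depends only on within-sample
    gene order and is therefore invariant to platform and normalization
    choices. A k-top-scoring-pairs classifier over pathway scores is trained
    repeatedly on resampled 70/30 splits of a two-class (poor/good prognosis)
    training cohort; models passing a balanced-accuracy filter are kept and
    vote on new samples, with the vote count thresholded into high- and
    low-risk groups. Includes survival-based evaluation (Harrell concordance,
    D-index, Kaplan-Meier/log-rank, fixed-horizon AUC), gene-dropout and
    monotone-transform robustness protocols, and a synthetic-cohort generator
    with pathway-structured class effects and class-dependent censored
    survival.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
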