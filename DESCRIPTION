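Package: ctratio
Title: Ratio-Based Molecular Classifiers for Paired Perinatal Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discovery and validation pipeline for birth-time molecular
    classifiers of later clinical outcome from paired case-control
    transcriptomic data. Implements paired empirical-Bayes moderated
    t-tests on quantile-normalized expression intensities with fold-change
    gating, gene-set scoring with down-weighting of genes shared between
    sets (sign-flip permutation significance), hypergeometric term
    enrichment with odds ratios, directional qRT-PCR confirmation of array
    candidates, and the central estimator: a linear discriminant classifier
    on log2 expression ratios (differences of -Ct values) built by
    exhaustive normalizer-gene search with repeated, nested cross-validation
    that maximizes average sensitivity at fixed specificities. Includes ROC
    utilities with a stratified bootstrap test for comparing two AUCs, a
    clinical-covariate comparator model, gestational-age subgroup analysis,
    and seeded synthetic-data generators emulating the matched-pair study
    design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
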