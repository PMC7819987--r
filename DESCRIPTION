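Package: fuzzyct
Title: Multihematoma Fuzzy Sign Detection and Matched-Cohort Analysis of
    Traumatic Hematoma Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the multihematoma fuzzy sign, a noncontrast CT marker of
    acute traumatic intraparenchymal hematoma (tICH) expansion, on Hounsfield
    unit volumes: threshold segmentation of hyperdense clots, connected
    component morphometry (volumes, Feret diameters, nearest-surface
    separations), the three-criteria sign call, and the 30%-or-5-mL expansion
    rule. Ships a ground-truthed CT phantom generator and a patient-level
    cohort simulator so the full observational validation pipeline can be
    exercised without clinical data: propensity-score estimation by
    iteratively reweighted least squares, 1:1 greedy caliper matching,
    standardized-difference balance reports, crude/adjusted/conditional
    matched odds ratios with McNemar tests, subgroup and interaction
    analyses, and rank-based ROC AUC with DeLong confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohortsim.R'
    'ctvolume.R'
    'effects.R'
    'expansion.R'
    'fuzzysign.R'
    'logistic.R'
    'matching.R'
    'phantoms.R'
    'pipeline.R'
    'roc.R'
    'segmentation.R'
    'utils.R'
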