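Package: morphosig
Title: Morphological Signatures of Drug Resistance from Cell Painting
    Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and application of directional morphological
    signatures of intrinsic drug resistance from high-content microscopy
    well profiles. Implements an image-based profiling workflow over
    Cell Painting style feature tables: median aggregation of single
    cells to well-level profiles, platemap annotation, per-plate z-score
    normalization and rule-based feature selection; covariate-adjusted
    per-feature signature discovery with per-covariate Tukey HSD
    post-hoc tests, Bonferroni thresholding and nuisance-covariate
    exclusion; single-sample rank-based (singscore style) signature
    scoring with an empirical permutation null; and classification
    evaluation (accuracy, average precision, ROC/AUROC) with
    feature-shuffled baselines. Includes a plate-structured synthetic
    data generator with planted resistance effects and nuisance
    covariates so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    matrixStats,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, FeatureExtraction, Classification
RoxygenNote: 7.3.3
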