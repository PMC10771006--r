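Package: dbppr
Title: Drug-Likeness Scoring from Hybrid Physicochemical and ADMET Property Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores chemical drug-likeness from a gamma-weighted hybrid of a
    six-value physicochemical profile and a twenty-value panel of ADMET
    endpoint probabilities (26 values in total).  Provides the full pipeline:
    SMILES standardization (salt stripping, charge neutralization,
    canonicalization, deduplication), molecular featurization (physicochemical
    properties, a pinned 200-descriptor vector, five fingerprint kinds, QED,
    Tanimoto and Murcko scaffold diversity statistics), a configurable
    20-endpoint ADMET classifier panel, profile-based drug-likeness
    classifiers (logistic regression, SVM, gradient-boosted trees with grid
    search), the evaluation machinery (ten-fold cross-validation, gamma
    sweeps, external validation, Mann-Whitney score comparisons,
    positive-unlabeled spy analysis, Shapley endpoint attribution), seeded
    synthetic fixtures, and a command-line interface for batch prediction and
    property-profile visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    glmnet,
    e1071,
    xgboost,
    ggplot2,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
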