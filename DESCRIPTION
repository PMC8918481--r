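Package: imbfuse
Title: Adaptive-Fusion Ensembles for Imbalanced Binary Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imbalance-aware metric learning and ensemble classification for
    binary datasets with skewed class sizes. Learns a discriminative linear
    feature space with an imbalance-weighted large-margin nearest-neighbor
    objective (ImLMNN), builds random feature subspaces on the transformed
    data, balances each subspace by SMOTE oversampling, trains linear
    max-margin base classifiers, and fuses their scores by a weighted vote
    whose weights are optimized with a genetic algorithm under an AUC
    fitness. Includes readers for delimited and KEEL-style data files, a
    synthetic imbalanced-data generator, stratified cross-validation with
    repeated runs, and a subspace-count sweep experiment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    ggplot2,
    pROC
Config/testthat/edition: 3
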