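Package: profam
Title: Protein Family Classification from Sequence-Derived Physicochemical Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for binary classification of protein families from
    primary sequence alone: greedy incremental redundancy reduction at a
    fractional identity threshold, extraction of 20-dimensional amino-acid
    composition and 188-dimensional composition/transition/distribution
    (CTD) physicochemical feature vectors, SMOTE oversampling for
    imbalanced classes, and random-forest classification with stratified
    cross-validation reporting sensitivity, specificity, accuracy,
    Matthews correlation and ROC AUC. Also provides the supporting
    analyses such a study needs: neighbor-joining phylogenies from
    p-distances with column-resampling bootstrap supports and midpoint
    rooting, and comparative-Ct (2^-dCt) qPCR group comparison with the
    exact Mann-Whitney U test. Deterministic synthetic-data generators
    make the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    randomForest,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
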