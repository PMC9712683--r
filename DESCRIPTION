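Package: afpkit
Title: Antifreeze Protein Prediction from Sequence and Evolutionary
    Profile Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and evaluating antifreeze-protein (AFP)
    classifiers from primary sequence and PSI-BLAST evolutionary profiles.
    Implements four feature encoders -- grouped amino acid composition
    (GAAC), dipeptide composition (DPC), pseudo tri-sliced PSSM
    (PseTS-PSSM) and segmented PSSM autocorrelation (Sg-PSSM-ACT) --
    together with recursive feature elimination driven by
    extremely-randomized-tree importances (ERT-RFE), tree-ensemble and
    gradient-boosted classifiers, and a stratified cross-validation
    evaluation harness reporting accuracy, sensitivity, specificity,
    F-measure, MCC, ROC and precision-recall summaries. A synthetic-data
    generator emulates labeled sequence sets and matching profiles with
    controllable class signal so the whole pipeline is testable without
    PSI-BLAST or database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    caret,
    graphics,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
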