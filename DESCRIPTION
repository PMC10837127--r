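Package: cellpick
Title: Label-Efficient Cell Selection for Single-Cell Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for choosing which cells to annotate when building
    training sets for single-cell (scRNA-seq, snRNA-seq, CyTOF) cell-type
    classifiers under a limited labelling budget. Implements
    uncertainty-driven active learning (entropy and maximum-probability
    query strategies with certainty-percentile batch selection),
    marker-ranked initial cell selection, adaptive reweighting (cluster-
    and marker-aware balanced subsampling without labels), pseudo-label
    self-training with entropy-based mislabel detection, and a
    benchmarking harness with imbalance designs, marker corruption,
    cell-type similarity, and five multiclass evaluation metrics. A
    negative-binomial / truncated-Gaussian synthetic-data generator with
    controllable type proportions, marker effect sizes and between-type
    similarity supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    nnet,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    mclust,
    pROC,
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
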