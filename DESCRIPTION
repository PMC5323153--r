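Package: hgimda
Title: Heterogeneous Graph Inference for miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations by integrating
    known associations, MeSH-based disease semantic similarity, miRNA
    functional similarity and Gaussian interaction-profile kernel similarity
    into a heterogeneous graph, then iterating a two-sided label propagation
    over the bipartite association matrix to its fixed point. Includes
    symmetric network normalization with a closed-form linear-solve oracle,
    global and local leave-one-out cross-validation with rank-based ROC/AUC,
    a block-structured synthetic-data generator so the whole pipeline is
    testable without external database downloads, and a command-line
    interface with simulate/predict/loocv subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
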