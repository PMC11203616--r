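Package: compgnn
Title: Composite Recurrent Graph Neural Networks for Molecular Property
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recurrent message-passing graph neural networks (GNN) and their
    composite (CGNN) variant for graph-level molecular property prediction.
    Nodes carry chemical-element labels grouped into eight periodic-table
    classes; the composite model dispatches each node's state update to a
    state-updating network dedicated to its element group, while a single
    output network averaged over nodes produces the graph-level prediction.
    Includes atom-grouping preprocessing (heterogenization and one-hot
    homogenization), full-batch Adam training with masked multi-task losses
    and validation-based early stopping, AUROC/average-precision/RMSE
    evaluation, hyperparameter grid search, a seeded generator of
    molecule-like synthetic graph datasets, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
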