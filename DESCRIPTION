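Package: fragprompt
Title: Fragment-Contrastive Pretraining and Functional-Group Prompt
    Learning for Molecular Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Self-supervised molecular representation learning from dual
    graph views: the atom-bond graph of a molecule and a BRICS
    fragment-reaction graph derived from it, trained with a normalized
    temperature-scaled contrastive objective. Downstream property
    prediction attaches a learnable functional-group prompt: 82 named
    SMARTS patterns are matched against each molecule, fused with the
    atomic embeddings of their match sites, and attended over by a
    learnable task token whose attention weights provide per-group
    interpretability. Includes scaffold-based dataset splitting, synthetic
    benchmark generation by BRICS recombination, and a command-line
    interface. Chemistry primitives are computed through RDKit via a
    bundled Python helper.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
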