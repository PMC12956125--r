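Package: mendelprio
Title: Mendelian Gene Prioritization from Gene-Level Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which human genes are Mendelian (capable of causing a
    monogenic disease) from gene-level features: aggregate variant
    pathogenicity scores, pathway and Gene Ontology biological-process
    membership, and protein language model embeddings. Features are screened
    with a tie-corrected Mann-Whitney z-score, a gradient-boosted regression
    model is trained under 10-fold cross-validation with an iterated
    precision-relabel round for the unlabeled genes, and results are
    evaluated with AUC, area under the precision-recall curve, empirical
    precision calibration and top-k enrichment factors. Also provides
    per-term network statistics (maximal protein-protein interaction degree,
    minimal evolutionary age) and a deterministic synthetic-data generator
    with planted signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xgboost
Suggests:
    fgsea,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
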