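Package: micronet
Title: Microbiome Network Inference, Consensus Networks, and Multi-Method Taxon Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microbial co-occurrence networks from taxon abundance
    tables with a conditional-mutual-information skeleton algorithm using
    quantile-based dynamic thresholds, combines networks from multiple
    inference methods into weighted consensus networks, quantifies network
    reproducibility with a bootstrap F1/Jaccard harness, and selects
    disease-associated taxa by combining seven machine-learning feature
    rankers with two network-centrality strategies. Includes a Gaussian-copula
    synthetic data generator with band-graph ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
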