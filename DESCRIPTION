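Package: phylocausal
Title: Phylogenetic Causal Analysis of Binary Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage phylogenetic comparative toolkit for binary traits:
    the D metric of phylogenetic signal with permutation and Brownian-threshold
    reference distributions; phylogenetic path analysis over competing causal
    directed acyclic graphs via d-separation basis sets, Fisher's C, the CICc
    information criterion and conditional model averaging; and Bayesian logistic
    mixed models with phylogenetic and Matern spatial random effects compared by
    K-fold cross-validation. Includes a synthetic-data generator (Yule trees,
    threshold-Brownian liabilities coupled through a causal graph, spatially
    autocorrelated fields) so every stage can be exercised and validated without
    external data, and an orchestration layer that reproduces the full
    signal - path analysis - mixed-model workflow from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
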