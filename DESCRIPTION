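Package: causalfoodq
Title: Causal Bayesian-Network Analysis of Food Quality Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for causal analysis of food quality tables: simulation of
    structural causal models with known ground truth, elastic-net screening of
    wide correlated predictor sets, score-based Bayesian-network structure
    learning (BIC hill climbing and structure MCMC), d-separation and backdoor
    adjustment, path-coefficient and average-causal-effect (ACE) estimation,
    do(x) intervention curves with ensemble uncertainty, and double
    machine-learning validation of total effects. Includes preset generators
    emulating wheat baking, fermented dairy and wine quality studies, and a
    declarative pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    glmnet,
    ranger,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
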