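Package: coocbench
Title: Benchmarking Co-Occurrence Network Inference on Simulated Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates steady-state microbial abundance data from generalized
    Lotka-Volterra dynamics on known interaction networks, infers association
    networks with correlation-based methods (Pearson, Spearman, MIC, SparCC)
    and graphical-model-based methods (partial correlations, sparse
    neighborhood selection with stability selection), and quantifies how well
    each method recovers the true interaction pattern using the area under the
    precision-recall curve and its baseline-corrected form. Includes network
    generators (Erdos-Renyi, Watts-Strogatz, static scale-free), signed
    interaction-matrix builders for five ecological community types, and a
    benchmark orchestrator with figure-level experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
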