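Package: bottlenet
Title: Information Bottlenecks in the Neural Control of Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how a small population of
    descending neurons can relay behavioral commands from the brain to a much
    larger set of motor units.  Behaviors are represented as rows of a sparse
    binary matrix (optionally with modular block structure), and a one-hidden-
    layer feed-forward network is trained to map one-hot commands through a
    bottleneck hidden layer onto the motor pattern.  The package estimates the
    critical bottleneck size needed to reproduce a behavioral repertoire,
    quantifies robustness to forced activation or inhibition of hidden units,
    and measures the state-dependency of perturbed outputs via discrete mutual
    information.  Includes generators for random and modular behavioral-matrix
    ensembles together with their Newman modularity and combinatorial entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
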