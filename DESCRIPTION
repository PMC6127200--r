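Package: qacolink
Title: Quantum-Inspired Ant Colony Optimization for Topological Link
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts missing links in undirected networks with a
    quantum-inspired ant colony optimization algorithm: per-node qubit
    registers updated by rotation gates bias tabu random walks whose
    pheromone trails, mixed with a quasi-local visibility index, score
    disconnected node pairs. Includes the common-neighbours,
    Cannistraci-Hebb and structural-perturbation-method baselines,
    Watts-Strogatz and nonuniform popularity-similarity network
    generators, and precision, precision-ranking, permutation-test and
    time-evolving snapshot evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
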