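Package: bnsim
Title: Boolean Regulatory Network Simulation with Attractor Sampling and
    Phenotype Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A logical-model engine for Boolean regulatory networks:
    parsing and serialization of BooleanNet-style rule files with compiled
    truth tables, deterministic synchronous, noisy synchronous, random-order
    asynchronous and biased asynchronous update schemes,
    environment-partitioned attractor detection by noisy state-space
    sampling with neighborhood scans and exhaustive enumeration oracles,
    entropy-maximizing gate reduction for subnetwork isolation, mutant
    network ensembles (node locks, link removals, gate-output flips),
    reversible environmental pulses, non-saturating stochastic inputs,
    partial knockdown/overexpression, and phenotype/cell-cycle event
    statistics.  Ships a self-contained tri-stable
    epithelial-mesenchymal-transition switch fixture and seeded random
    network generators so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
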