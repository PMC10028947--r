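Package: ppinet
Title: Network Propagation and In Silico Repression for Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for interactomic analysis of protein-protein
    interaction (PPI) networks. Parses StringDB and BioGRID edge lists,
    filters large networks to phenotype-specific subgraphs by node score or
    expression, propagates seed-protein signal by random walk with restarts
    over a sparse column-stochastic transition matrix, assesses affinity
    significance against a degree-matched bootstrapped null with empirical
    p-values and multiplicity adjustment, scores nodes by degree,
    betweenness centrality and thermodynamic network potential (Gibbs free
    energy), and ranks candidate drug targets by in-silico repression: the
    change in total network potential when a node is removed, with a
    degree-preserving rewired-graph null. Includes seeded synthetic graph
    and expression generators plus a command-line front end so every
    analysis runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
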