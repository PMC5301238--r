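Package: sergraph
Title: Excitable SER Dynamics on Graphs with a Relative Threshold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a three-state (susceptible,
    excited, refractory) cellular automaton on undirected graphs in which a
    node of degree k is excited when at least a fraction kappa of its
    neighbours are excited. Provides Erdos-Renyi and Barabasi-Albert graph
    generation, the layered (BFS) view of a network seen from an input node,
    topological predictors of the onset of excitation propagation
    (minimax-path bottleneck degrees) and of the limit of self-sustained
    activity (maximal degrees), binary-search measurement of both transition
    points, ensemble prediction-quality scans, and closed-form mean-field
    predictions (steady-state activity density, multiple-excitation
    probability, output saturation level). The simulation core is written in
    C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
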