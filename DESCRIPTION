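Package: infofrag
Title: Information Fragmentation Analysis and Flow Graphs for Discrete Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Locates, quantifies and traces information distributed (and
    encrypted) across the nodes of a discrete dynamical network. Provides
    Shannon entropy, mutual information and co-information on maximum
    likelihood joint-state tables, a power-set search for distinct
    informative sets (DISs), fragmentation values and fragmentation
    matrices, and information-flow graphs with connectome-based
    disambiguation of redundant predictive sets. Also ships the digital
    evolution testbed used to generate analyzable networks: genome-encoded
    Markov Brains and discretized recurrent networks, the n-Back memory
    task and the Block Catch active-perception task, a tournament-selection
    genetic algorithm with line-of-descent reconstruction, and mutational
    robustness scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
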