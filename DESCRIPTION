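Package: gotnet
Title: Graphlet-Orbit Transitions for Temporal Network Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compare temporal networks by the trajectories of node roles
    (graphlet automorphism orbits) across consecutive snapshots. Builds
    catalogs of all connected k-node graphlets with their orbit partitions,
    enumerates induced subgraph occurrences per snapshot, constructs
    orbit-transition matrices and the orbit-transition-agreement (OTA)
    similarity, alongside static baselines (graphlet degree distributions
    with GDD-agreement, and network-motif fingerprints over a
    degree-preserving null model). Includes seeded generators for evolving
    Erdos-Renyi, Barabasi-Albert and Watts-Strogatz models and a grouping
    experiment with PCA, precision-recall sweeps and AUPR.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
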