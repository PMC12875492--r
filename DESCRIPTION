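Package: netcent
Title: Normalized Network Centralization Measures and Their Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes eleven normalized measures of network centralization
    (degree, betweenness and closeness centralization, hub dominance, hub
    formation tendency, degree variance, degree entropy, Gini coefficient of
    the degree sequence, assortativity-based hubness, eigenvector centrality
    dispersion, and spectral natural connectivity) on simple undirected
    graphs, all calibrated to the unit interval with the star graph as the
    maximally centralized reference. Provides a dual evaluation framework:
    a compliance battery that tests each measure against six postulates of
    centralization over an exhaustive corpus of small labeled graphs plus a
    registry of known counterexamples, and a numerical battery that tracks
    each measure across canonical graph families (star, ring, complete, and
    single-edge perturbations thereof) as order grows. Axiomatic and
    numerical scores are combined into a weighted overall ranking. Includes
    readers for edge-list, GML and GraphML files and a largest-component
    pipeline for applying the path-based measures to real networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
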