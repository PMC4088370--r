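Package: PINzones
Title: Metric-Space Zone Decomposition of Protein Interaction Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models undirected protein interaction networks as metric
    spaces under the shortest-path (hop count) distance. Finds the
    topological centre (the eccentricity-minimising protein), partitions
    proteins into zones by distance from the centre, and summarises each
    zone's graph structure (size, degree statistics, degree-1 "quills").
    Maps user-supplied annotation sets (essential genes, disease genes,
    drug targets, consistently expressed cancer genes) onto zones,
    producing count/percentage distribution tables, pooled two-proportion
    z-tests between zones, and hypergeometric over-representation analysis
    with Bonferroni correction. Includes a synthetic core-periphery
    network generator with planted ground truth so the whole pipeline is
    testable without external data, plus readers/writers for edge lists
    (TSV/SIF), GMT gene sets, presence/absence call matrices, zone
    assignment tables and KEGG Mapper colour files, and a YAML-driven
    end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Pathways, SystemsBiology
RoxygenNote: 7.3.3
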