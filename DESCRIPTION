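Package: netscreen
Title: Topological Hub Screening for Network Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles herb-target / disease-target / protein-protein
    interaction networks for network-pharmacology studies and screens them
    for hubs and major hubs with a two-stage topological filter (twofold
    median-degree cutoff, then strict median thresholds on degree,
    betweenness, closeness and coreness of the hub-induced subnetwork).
    Includes an Erdos-Renyi G(n,m) null model that preserves node and edge
    counts, hypergeometric over-representation analysis of the selected
    major hubs against GMT gene sets with Benjamini-Hochberg control, a
    synthetic study-shaped data generator with planted hubs and planted
    enriched pathways for validation, and GraphML/SIF export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
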