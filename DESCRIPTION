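Package: adnet
Title: Association Networks Linking Anaerobic Digester Performance to
    Microbial Interaction Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers microbial association networks from taxon-by-sample
    abundance tables of anaerobic digester communities and relates their
    topology to digester performance. Builds Spearman correlation networks
    with Benjamini-Hochberg false-discovery-rate control and a random matrix
    theory (RMT) threshold chosen from the nearest-neighbour eigenvalue
    spacing distribution; compares topology against uniform random-graph
    ensembles; classifies edges as global or group-specific by an
    omission-score permutation procedure; detects modules and module-hub
    (candidate keystone) taxa; computes between-taxa edge effect sizes; and
    runs gene-significance Mantel and partial Mantel tests of connectivity
    against environmental and performance parameters. A synthetic community
    generator with planted correlation modules, group-specific couplings and
    performance-driver taxa provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    vegan,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
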