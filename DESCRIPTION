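Package: fibronet
Title: Agent-Based Spring-Network Modelling of Pulmonary Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Hybrid agent-based / elastic spring-network model of progressive
    pulmonary fibrosis.  Mechanosensitive fibroblast-like agents migrate
    randomly on a prestressed two-dimensional elastic network, read local
    spring stiffness and strain through Hill-type activation functions,
    deposit or digest extracellular matrix, proliferate and die.  The package
    implements the lumped single-element difference-equation system together
    with its fixed points, fibrotic-threshold and bifurcation analysis;
    procedural Voronoi and honeycomb network generation with prestress and
    reaction-force boundary conditions; a deterministic force-relaxation
    equilibrium solver with rupture pruning and a strain-energy stiffness
    assay; injury protocols and replicate experiment drivers; and rendering
    of synthetic histology and phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
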