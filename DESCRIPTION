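Package: knobsocket
Title: Knob-Socket Packing Analysis of Alpha-Helical Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Packing", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps the packing of alpha-helical protein-protein interfaces with
    the knob-socket model. Atomic contacts are derived from a Delaunay
    tessellation of heavy-atom coordinates, lifted to a typed residue contact
    graph, and classified into three-residue 2:1 sockets, four-residue 2:1+1
    knob-socket motifs, and four-residue pockets. The package builds
    per-complex interface packing maps, helical lattice diagrams, socket
    centroid distance tables, conserved-groove models, and central-glycine
    anchored consensus models of BH3 ligands bound to pro-survival BCL-2
    family receptors. A synthetic-structure generator with known ground-truth
    motifs makes the whole pipeline testable without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
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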