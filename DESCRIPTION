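Package: acam
Title: Apposed-Cortex Adhesion Model of Epithelial Tissue Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 2D epithelial tissue mechanics with an apposed-cortex
    adhesion model. The junctional actomyosin cortex of every cell is a
    closed, discretised morphoelastic rod (a viscoelastic rope-loop) and
    neighbouring cortices are coupled by explicit Hookean adhesion bonds
    with saturation and finite-lifetime turnover. Quasi-static energy
    minimisation with per-step rest-length relaxation reproduces vertex
    geometry, tissue fracture under uniform contractility, active T1
    neighbour exchanges driven by junctional contractility, adhesion-
    timescale-dependent slippage and area loss, and rosette formation.
    Includes tissue factories for standard fixtures, activity protocols,
    observables (junction maps, vertex openings, tensions, kymographs)
    and snapshot/trace serialisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
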