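Package: cryptdrift
Title: Individual-Cell-Based Simulation of Clonal Competition in
    Intestinal Crypts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Off-lattice, single-cell-based simulation of the mouse small
    intestinal crypt. Cells live on a fixed cylinder-plus-hemisphere basal
    membrane, move under adhesion/repulsion and active migration biases,
    grow under contact inhibition, divide, and adopt lineage fates (stem,
    enterocyte, goblet, Paneth) from positional Wnt thresholds and
    contact-count Notch rules. Paneth-cell lifespan can be intrinsic or
    contact-controlled. Heritable mutation profiles are injected into stem
    cells, and the clonal-competition machinery builds stem-cell division
    forests, detects monoclonal conversion, computes positional
    distributions f(P), w(P), p(P), positional advantage ratios,
    advantaged-stem-cell counts and mutation-fixation statistics, and
    exports phylogenies as Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
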