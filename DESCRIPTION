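Package: sheetkit
Title: Design Validation and Geometry Analysis for Self-Assembled DNA Nanosheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the design and structural analysis of DNA nanosheets
    assembled from three-strand F-units. Encodes the F-unit design (core,
    arm, and sticky-end duplex lengths, stoichiometry, annealing schedules),
    computes nearest-neighbor duplex melting temperatures and the implied
    hierarchical hybridization order, and predicts idealized lattice geometry
    (pore quadrilateral sides and diagonals, hydrophobic-anchor spacings,
    open-area porosity). Reads and writes coarse-grained oxDNA topology and
    configuration files and computes junction planarity, inter-arm angles,
    pore diagonals and internal angles, and corner-plane planarity from
    configurations. Analyzes AFM-style one-dimensional height profiles
    (pore spacing, discrete duplex layer counts) and interfacial shear
    rheology time sweeps, including extrapolation of interfacial storage
    moduli to bulk and porosity-corrected Young's moduli. Seeded synthetic
    generators emulate every input with exported ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
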