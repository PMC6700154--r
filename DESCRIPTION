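Package: mempot
Title: Membrane-Protein Statistical Potentials and Residue Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives smoothed, threshold-guarded, distance-dependent
    statistical potentials separately from the transmembrane and
    extramembrane regions of integral membrane protein structures,
    including amino-acid group variants with radius-based distance
    shifts.  Computes global and per-residue folding free energies
    under these potentials and classifies residues as trans- or
    extramembrane with a linear localization index under strict
    leave-one-out cross-validation.  Ships a deterministic synthetic
    structure generator so the whole pipeline is testable without any
    external dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
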