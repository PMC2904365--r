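Package: terndock
Title: Rigid-Body Docking and Interface Analysis for TCR-Peptide-MHC
    Ternary Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and selects models of ternary T-cell-receptor /
    peptide / MHC class II complexes by FFT shape-complementarity
    rigid-body docking with a Coulombic binary filter, biology-driven
    distance-constraint and peptide-register pose filtering, ranking of
    survivors by pairwise interaction energy and buried interface
    accessible surface area, interface characterization (van der Waals
    contacts, hydrogen bonds with per-frame occupancy, per-frame
    RMSD/RMSF), and simplified computational alanine scanning for
    interface hotspots.  Ships a deterministic synthetic-benchmark
    generator with planted ground truth so every stage is testable
    without external coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
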