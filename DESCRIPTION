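Package: perturbxtal
Title: Comparative Crystallography of Temperature- and Pressure-Perturbed Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative comparison of crystal structures of the
    same protein determined under different physical conditions (e.g. high
    temperature versus high pressure against a cryogenic reference).
    Computes unit-cell and protein molecular volumes and their percent
    changes, classifies ordered waters as shared or unique using
    crystal-symmetry-aware minimum distances, profiles per-residue C-alpha
    displacements and multi-structure RMSF, samples electron-density maps
    around side-chain chi1 rotations (Ringer-style curves) with Pearson
    correlation comparisons, assigns side-chain rotamer names and censuses
    rotamer changes, and embeds structure sets in a reduced torsion-angle
    space by principal component analysis. A synthetic crystal and
    density-map generator with recorded ground truth makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
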