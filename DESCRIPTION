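Package: epigraft
Title: Epitope Grafting onto Beta-Solenoid Scaffolds for Conformation-Specific Immunogen Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based design of immunogens that display
    conformational surface epitopes of parallel in-register amyloid fibrils on
    an innocuous beta-solenoid scaffold. Measures cross-beta fibril geometry
    (helical axis, axial rise and twist, beta-strand segmentation, in-register
    verification), detects the beta-solenoid rung pseudo-repeat, scores
    per-residue solvent accessibility to find graftable surface positions, and
    generates two-rung "stacked graft" substitution sets in which the same
    donor residue is placed on both rungs so that scaffold self-stacking mimics
    the donor fibril's in-register stacking. Ships the four published
    HET-s(218-289)-based alpha-synuclein vaccine candidates (alpha-SC3,
    alpha-SC6, alpha-SC8, alpha-SC9) as presets, plus deterministic synthetic
    coordinate generators for idealized beta-solenoids and fibrils.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
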