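Package: xbnmr
Title: NMR Characterisation of Weak Intramolecular Halogen Bonds in
    Folding Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the solution-NMR characterisation of very weak
    intramolecular interactions, exemplified by an iodine-ether halogen
    bond embedded in a cooperatively folding beta-hairpin peptide.
    Implements two-state thermal melting analysis of variable-temperature
    chemical shifts (per-proton and global fits, folding free energies,
    relative stabilities from paired melting curves, amide temperature
    coefficients), NOE build-up initial-rate distance calibration and
    Karplus coupling prediction, NAMFIS-style deconvolution of
    population-averaged restraints over a conformer pool, residual
    dipolar coupling alignment-tensor fitting by singular value
    decomposition with Cornilescu Q and condition-number diagnostics and
    chi-square-penalised sub-ensemble selection, geometric fold and
    halogen-bond classification of conformers, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
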