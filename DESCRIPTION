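Package: pepmicelle
Title: NMR-Derived Restraints and Conformational Analysis of
    Micelle-Bound Peptide Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts solution-NMR observables measured for small
    disulfide-bridged peptides in detergent micelles into conformational
    restraints, and analyses the resulting conformational ensembles.
    Scalar couplings are translated into chirality-aware phi torsion
    intervals, NOE volumes into calibrated distance bounds, and amide
    temperature coefficients into hydrogen-bond classes.  Ensemble
    analyses cover backbone torsions, beta-turn detection and Lewis-type
    classification (including primed types favoured by d-residues),
    hydrogen-bond occupancies, radii of gyration, aromatic ring-pair
    descriptors, and periodic-box solvation statistics (radial
    distribution functions and hydration numbers).  A geometry-only
    synthetic-data generator builds ideal peptides with planted torsions
    and toy micelle/water boxes with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
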