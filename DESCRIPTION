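Package: dynofp
Title: Dynamic Interaction Fingerprints and Activation-State Analysis for
    GPCR-Ligand Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-frame geometric detection of protein-ligand interactions
    (ionic, hydrogen bond, water-mediated hydrogen bond, hydrophobic,
    cation-pi, steric clash) in molecular-dynamics trajectories, with
    occurrence-frequency statistics across simulation replicates,
    interaction-distance quality profiles, rescoring of docking poses
    against reference interaction fingerprints, and crystal-referenced
    TM6-deflection classification of class-A GPCR activation states.
    Includes Ballesteros-Weinstein residue numbering, sequence
    identity/similarity utilities, and a synthetic trajectory generator
    with scheduled ground-truth contact occupancies and state fractions
    for validating every analysis stage without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
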