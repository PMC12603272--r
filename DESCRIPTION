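Package: groovebind
Title: 3D-QSAR Affinity Prediction and Binding Analysis for DNA
    Minor-Groove Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for predicting the DNA minor-groove binding affinity
    of small molecules from aligned ligand/DNA-decamer complexes:
    comparative molecular field (CoMFA-style) steric and electrostatic
    probe grids, partial least squares (NIPALS) regression of pK_D with
    leave-one-out and external validation, docked-pose assessment
    (symmetry-corrected RMSD, redocking accuracy, score-affinity
    correlation) and QSAR-based pose rescoring to predicted pK_D/K_D.
    Also implements the supporting binding-assay mathematics:
    tight-binding (quadratic) titration simulation and fitting with a
    saturation-stoichiometry breakpoint, fluorescence polarization, and
    cell doubling time. A synthetic-data module generates every input the
    pipeline consumes, so all stages run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    bio3d,
    clue,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
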