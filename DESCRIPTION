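Package: mdmotifs
Title: Hydrogen-Bond Motif Discovery and Conformational State Analysis for
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis workbench for molecular dynamics trajectories of
    protein-DNA complexes such as the MutS-alpha (MSH2-MSH6) damage-recognition
    dimer.  Detects geometric hydrogen bonds, collapses them into binary
    residue-pair feature matrices, and mines class-discriminative contacts with
    prunable binary classification trees.  Clusters conformations with
    intelligent Minkowski-weighted K-means (Amorim-Hennig clustering with
    explicit rescaling), computes RMSF profiles, dynamic cross-correlation
    matrices, principal-component free-energy landscapes, and aromatic
    stacking-state fractions, and ships a seeded synthetic-trajectory generator
    with planted structure for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
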