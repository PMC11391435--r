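Package: mdcompare
Title: Comparative Analysis of Molecular Dynamics Trajectories Across
    Protein States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for contrasting molecular dynamics ensembles of a
    protein complex simulated in several states (e.g. unmodified,
    point-mutated, phosphorylated): backbone superposition and
    RMSD/RMSF flexibility profiling with order-dependent difference
    thresholds, simplified per-frame secondary-structure fractions,
    geometric hydrogen-bond occupancy and water-bridge scanning,
    Shrake-Rupley solvent-accessible surface area, MM/PBSA-style
    interaction-energy summaries with per-residue decomposition,
    ensemble machine-learning scoring of interfacial residue
    importance with a three-category residue classification, exact
    small-sample one-tailed Mann-Whitney U tests, and a synthetic
    two-chain ensemble generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    glmnet,
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
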