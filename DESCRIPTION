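Package: ifpsim
Title: Similarity Measures and Sum of Ranking Differences for Interaction
    Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing binary similarity measures on protein-ligand
    interaction fingerprints (SIFt-style bitstrings). Provides fingerprint
    input/output, bit-selection schemes (ALL/WO1/WO3), residue- and
    interaction-based filtering rules (RES/INTS), a catalog of 44 rescaled
    binary similarity coefficients with symmetricity and metricity classes,
    column-wise data pretreatment (autoscaling, range scaling, rank
    transformation), the sum of ranking differences (SRD) algorithm with
    consensus (min/max) reference fusion, fivefold cross-validation and a
    permutation (randomization) test, ROC-AUC scoring, a full factorial
    evaluation grid with factorial ANOVA summaries, and a seeded generator of
    synthetic fingerprint datasets emulating active/decoy virtual-screening
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
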