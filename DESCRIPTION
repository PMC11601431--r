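Package: protpka
Title: Structure-Based Prediction of Protein pKa Values and Protonation States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts pKa values and protonation states of the six titratable
    amino acids (Asp, Glu, His, Cys, Tyr, Lys) from protein structures.
    Computes physicochemical microenvironment features of titratable sites
    (burial, solvent accessibility, polar/charged neighbour counts and
    distances), trains separate acid and base gradient-boosted tree
    regressors under a leakage-free stratified holdout protocol, and trains
    a residue-centred atom-graph attention ensemble on pKa shifts.
    Includes Henderson-Hasselbalch protonation-state classification with
    the critical-error-rate metric, conformer-based training-set
    augmentation, and seeded synthetic-structure generators so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
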