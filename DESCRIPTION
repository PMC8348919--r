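Package: xoiqsar
Title: Field-Based 3D-QSAR, Validation Statistics and Virtual-Screening
    Funnel for Xanthine Oxidase Inhibitors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the in-silico chain used to
    analyse dihydropyrimidine xanthine-oxidase inhibitors: lattice-based
    molecular interaction fields (CoMFA/CoMSIA style) with partial
    least-squares regression and leave-one-out cross-validation, the full
    internal/external QSAR validation statistic suite (rm2 family,
    r_pred2, through-origin regressions, threshold battery), pharmacophore
    matching with decoy-set enrichment scoring (EF and Guner-Henry),
    a staged virtual-screening funnel with ADME rule filters, and
    post-molecular-dynamics trajectory and MM-PBSA energy metrics
    (Kabsch RMSD, RMSF, radius of gyration, hydrogen-bond counting).
    Includes seeded synthetic-data generators so the whole pipeline is
    testable without proprietary upstream tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    methods,
    stats,
    utils,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    ChemmineR
SystemRequirements: python with rdkit (used for conformer embedding and
    substructure matching); openbabel (via ChemmineOB)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
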