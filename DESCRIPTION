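Package: melscreen
Title: Machine-Learning Virtual Screening of Melatonin Bioactivity with
    Cardiovascular Cross-Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for triaging compounds with melatonin
    receptor activity from heterogeneous ChEMBL-style bioactivity tables.
    Normalizes mixed-unit activity measurements into a -log10 molar potency
    score, averages it across melatonin receptor subtypes, encodes every
    activity record as a 60-variable feature vector, augments the training
    data with an artificial inactive population harvested from GPCR
    inactivity evidence, fits random-forest classification and regression
    models, screens a compound universe with a per-compound countRatio and
    combined melatonin score, and cross-filters hits against cardiovascular
    assays, exporting hit tables and a compound-assay bipartite graph. A
    synthetic ChEMBL-emulating data generator with known ground truth makes
    every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    graphics,
    igraph,
    jsonlite,
    pROC,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
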