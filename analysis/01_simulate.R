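#!/usr/bin/env Rscript
# Step 1 — simulate the study universe.
#
# Generates the default synthetic ChEMBL-emulating universe: 2,000
# compounds (30% truly melatonin-active), 30 melatonin receptor assays
# across the three subtypes, a 50-assay GPCR inactivity panel, and 40
# cardiovascular assays, with mixed nM/uM/ug-mL units and censored records.
# Writes the three internal-dialect tables plus the ground truth.

suppressMessages(library(melscreen))

seed <- 2024L
dir.create("results/synthetic", showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
u <- generate_synthetic_chembl(cfg)

write_activity_table(u$activities, "results/synthetic/activities.tsv")
write_compound_table(u$compounds, "results/synthetic/compounds.tsv")
write_assay_table(u$assays, "results/synthetic/assays.tsv")
readr::write_tsv(u$truth$compounds, "results/synthetic/truth_compounds.tsv")
readr::write_tsv(u$truth$assays, "results/synthetic/truth_assays.tsv")

cat("universe:", nrow(u$activities), "activity records,",
    nrow(u$compounds), "compounds,", nrow(u$assays), "assays\n")
cat("true actives:", sum(u$truth$compounds$true_active),
    "| cv-potent actives:", sum(u$truth$compounds$is_cv_potent),
    "| gpcr-eligible inactives:", sum(u$truth$compounds$gpcr_eligible), "\n")
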