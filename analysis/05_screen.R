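#!/usr/bin/env Rscript
# Step 5 — virtual screening of the whole record universe.
#
# Every record is scored by the trained bundle and aggregated per compound.
# The final melatonin score is the measured averaged potency score where
# one exists, otherwise countRatio x mean predicted score. Compounds with
# score > 4 are hits; hits carrying a drug name are listed separately.

suppressMessages(library(melscreen))

records <- read_activity_table("results/synthetic/activities.tsv", "internal")
compounds <- read_compound_table("results/synthetic/compounds.tsv", "internal")
assays <- read_assay_table("results/synthetic/assays.tsv", "internal")
averages <- readr::read_tsv("results/subtype_averages.tsv",
                            show_col_types = FALSE)
bundle <- readRDS("scratch/model_bundle.rds")

linked <- link_tables(records, compounds, assays)
schema <- build_schema()
encoded <- encode_rows(linked$view, schema, averages)

results <- screen(bundle, encoded, averages)
hist_tbl <- score_histogram(results)
named <- named_drug_hits(results, compounds)

readr::write_tsv(results, "results/screen_results.tsv", na = "")
readr::write_tsv(hist_tbl, "results/score_histogram.tsv")
readr::write_tsv(named, "results/named_drug_hits.tsv", na = "")

cat("screened", nrow(results), "compounds over", nrow(encoded),
    "records\n")
cat("hits (melatonin score > 4):", sum(results$is_hit), "\n")
cat("hits with a drug name:", nrow(named), "\n")
cat("top named hits:\n")
print(as.data.frame(utils::head(
  named[, c("compound_id", "pref_name", "melatonin_score")], 8)))
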