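#!/usr/bin/env Rscript
# Step 3 — build the 60-variable validation set.
#
# Every record of a melatonin-related compound (one with at least one
# scorable receptor-subtype record) becomes one 60-feature row labelled by
# whether the compound's averaged potency score exceeds 4. The negative
# population is then augmented with one inactive row per compound that is
# inactive in at least 10 distinct GPCR assays.

suppressMessages(library(melscreen))

seed <- 2024L
records <- read_activity_table("results/synthetic/activities.tsv", "internal")
compounds <- read_compound_table("results/synthetic/compounds.tsv", "internal")
assays <- read_assay_table("results/synthetic/assays.tsv", "internal")
averages <- readr::read_tsv("results/subtype_averages.tsv",
                            show_col_types = FALSE)
scores <- readr::read_tsv("results/potency_scores.tsv",
                          show_col_types = FALSE)

linked <- link_tables(records, compounds, assays)
schema <- build_schema()
encoded <- encode_rows(linked$view, schema, averages)

subtype_scored <- scores$compound_id[
  scores$target_id %in% melatonin_subtype_ids(scores$target_id)]
mel_compounds <- unique(c(averages$compound_id, subtype_scored))
base_rows <- encoded[encoded$compound_id %in% mel_compounds, ]
attr(base_rows, "schema_fingerprint") <- attr(encoded, "schema_fingerprint")
attr(base_rows, "label_threshold") <- 4

eligible <- find_inactives(records, assays, scores = scores)
eligible <- eligible[!eligible$compound_id %in% mel_compounds, ]
target <- min(sum(eligible$eligible),
              default_augment_count(length(mel_compounds)))
validation <- augment(base_rows, eligible, linked$view, schema,
                      target_count = target, seed = seed)

write_validation_set(validation, schema, "results/validation_set.tsv")
readr::write_tsv(eligible, "results/eligible_inactives.tsv")

cat("validation set:", nrow(validation), "rows (",
    attr(validation, "n_augmented"), "augmented inactives )\n")
print(table(validation$label))
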