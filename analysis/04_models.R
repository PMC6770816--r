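#!/usr/bin/env Rscript
# Step 4 — split 80/20, train the random forests, evaluate held-out
# prediction quality.
#
# The classifier predicts the activity label, the regressor the activity
# score; the held-out records' truth is removed before prediction and
# compared afterwards: per-record and per-compound correlation, the
# confusion matrix, and the countRatio distribution by true label.

suppressMessages(library(melscreen))

seed <- 2024L
validation <- readr::read_tsv("results/validation_set.tsv",
                              show_col_types = FALSE)
schema <- build_schema()
attr(validation, "schema_fingerprint") <- schema_fingerprint(schema)

split <- split_rows(validation, seed = seed)
train <- validation[validation$record_id %in% split$train_record_ids, ]
test <- validation[validation$record_id %in% split$test_record_ids, ]
attr(train, "schema_fingerprint") <- schema_fingerprint(schema)
attr(test, "schema_fingerprint") <- schema_fingerprint(schema)

bundle <- train_models(train, schema, seed = seed)
ev <- evaluate_models(bundle, test)

dir.create("scratch", showWarnings = FALSE)
write_bundle(bundle, "scratch/model_bundle.rds")
readr::write_tsv(ev$count_ratio_by_label, "results/count_ratio_by_label.tsv")
jsonlite::write_json(
  list(n_train = nrow(train), n_test = nrow(test),
       record_pearson = ev$record_pearson,
       record_spearman = ev$record_spearman,
       compound_pearson = ev$compound_pearson,
       accuracy = ev$accuracy,
       confusion = as.data.frame(ev$confusion)),
  "results/model_evaluation.json", auto_unbox = TRUE, digits = NA
)

print(ev)
cat("countRatio by true label:\n")
print(as.data.frame(ev$count_ratio_by_label))
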