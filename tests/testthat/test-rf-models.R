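test_that("the 80/20 split partitions records exactly", {
  rows <- separable_rows(100)
  sp <- split_rows(rows, seed = 1)
  expect_length(sp$train_record_ids, 80L)
  expect_length(sp$test_record_ids, 20L)
  expect_length(intersect(sp$train_record_ids, sp$test_record_ids), 0L)
  expect_setequal(c(sp$train_record_ids, sp$test_record_ids),
                  rows$record_id)

  sp5 <- split_rows(separable_rows(5), seed = 1)
  expect_length(sp5$train_record_ids, 4L)
  expect_length(sp5$test_record_ids, 1L)

  expect_identical(split_rows(rows, seed = 9)$train_record_ids,
                   split_rows(rows, seed = 9)$train_record_ids)
  expect_error(split_rows(rows, seed = 1, fraction = 1), "between 0 and 1")
})

test_that("disjointness and coverage hold over 100 seeds", {
  rows <- separable_rows(73)
  for (seed in 1:100) {
    sp <- split_rows(rows, seed = seed)
    expect_length(intersect(sp$train_record_ids, sp$test_record_ids), 0L)
    expect_equal(sort(c(sp$train_record_ids, sp$test_record_ids)),
                 sort(rows$record_id))
  }
})

test_that("a separable score function is learned almost perfectly", {
  rows <- separable_rows(300)
  schema <- build_schema()
  bundle <- train_models(rows, schema, seed = 5)
  pred <- predict_records(bundle, rows)
  acc <- mean((pred$call == "active") == (rows$label == "active"))
  expect_gt(acc, 0.95)
})

test_that("shuffled labels give chance-level held-out accuracy", {
  rows <- separable_rows(400, seed = 2)
  withr::local_seed(11)
  rows$label <- sample(rows$label)
  rows$activity_score <- sample(rows$activity_score)
  sp <- split_rows(rows, seed = 3)
  train <- rows[rows$record_id %in% sp$train_record_ids, ]
  test <- rows[rows$record_id %in% sp$test_record_ids, ]
  attr(train, "schema_fingerprint") <- attr(rows, "schema_fingerprint")
  bundle <- train_models(train, build_schema(), seed = 5)
  pred <- predict_records(bundle, test)
  acc <- mean(pred$call == test$label)
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("training is deterministic under a fixed seed", {
  rows <- separable_rows(150)
  schema <- build_schema()
  b1 <- train_models(rows, schema, seed = 7)
  b2 <- train_models(rows, schema, seed = 7)
  expect_identical(predict_records(b1, rows), predict_records(b2, rows))
})

test_that("single-class training data is rejected", {
  rows <- separable_rows(50)
  rows$label <- "active"
  expect_error(train_models(rows, build_schema(), seed = 1),
               "single class")
})

test_that("prediction ignores any label columns and handles degenerate rows", {
  rows <- separable_rows(120)
  schema <- build_schema()
  bundle <- train_models(rows, schema, seed = 5)
  # identical feature rows give identical outputs
  twice <- rows[c(1, 1), ]
  p <- predict_records(bundle, twice)
  expect_equal(p$call[1], p$call[2])
  expect_equal(p$predicted_score[1], p$predicted_score[2])
  # label columns flipped: outputs unchanged
  flipped <- rows
  flipped$label <- rev(flipped$label)
  flipped$activity_score <- rev(flipped$activity_score)
  expect_identical(predict_records(bundle, flipped)$predicted_score,
                   predict_records(bundle, rows)$predicted_score)
  # all-sentinel row scores without crashing
  sent <- rows[1, ]
  sent[, schema$name] <- -1
  expect_no_error(predict_records(bundle, sent))
})

test_that("a schema mismatch is refused", {
  rows <- separable_rows(60)
  bundle <- train_models(rows, build_schema(), seed = 2)
  alien <- rows
  attr(alien, "schema_fingerprint") <- "something-else"
  expect_error(predict_records(bundle, alien), "different schema")
})

test_that("countRatio aggregation matches hand values", {
  pred <- tibble::tibble(
    record_id = sprintf("R%d", 1:9),
    compound_id = c(rep("A", 4), rep("B", 5)),
    call = c("active", "active", "active", "inactive", rep("inactive", 5)),
    predicted_score = c(5, 7, 5, 7, rep(1, 5))
  )
  agg <- aggregate_compound(pred)
  expect_equal(agg$count_ratio[agg$compound_id == "A"], 0.75)
  expect_equal(agg$count_ratio[agg$compound_id == "B"], 0)
  expect_equal(agg$mean_predicted_score[agg$compound_id == "A"], 6)
})

test_that("aggregation agrees with a naive per-compound loop on random tables", {
  withr::local_seed(19)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    pred <- tibble::tibble(
      record_id = sprintf("R%03d", seq_len(n)),
      compound_id = sample(sprintf("C%d", 1:5), n, replace = TRUE),
      call = sample(c("active", "inactive"), n, replace = TRUE),
      predicted_score = runif(n, 0, 9)
    )
    agg <- aggregate_compound(pred)
    for (cid in unique(pred$compound_id)) {
      sub <- pred[pred$compound_id == cid, ]
      expect_equal(agg$count_ratio[agg$compound_id == cid],
                   sum(sub$call == "active") / nrow(sub))
      expect_equal(agg$mean_predicted_score[agg$compound_id == cid],
                   mean(sub$predicted_score))
    }
  }
})

test_that("evaluation is exact for perfect and degenerate predictors", {
  # oracle substitution: predictions identical to the truth
  pred <- tibble::tibble(
    record_id = sprintf("R%d", 1:6),
    compound_id = sprintf("C%d", 1:6),
    call = c(rep("active", 3), rep("inactive", 3)),
    predicted_score = c(7, 8, 6, 1, 0, 2)
  )
  rows <- tibble::tibble(
    record_id = pred$record_id, compound_id = pred$compound_id,
    label = pred$call, activity_score = pred$predicted_score
  )
  # bypass the models: check the metric arithmetic directly
  agg <- aggregate_compound(pred, tibble::tibble(
    compound_id = rows$compound_id, average_score = rows$activity_score))
  expect_equal(stats::cor(agg$mean_predicted_score, agg$actual_score), 1)
  cr_active <- agg$count_ratio[match(c("C1", "C2", "C3"),
                                     agg$compound_id)]
  expect_equal(cr_active, c(1, 1, 1))

  # constant predictions: correlation undefined, reported as absent
  rows2 <- separable_rows(40)
  rows2$activity_score <- 5
  rows2$label <- rep(c("active", "inactive"), 20)
  bundle <- train_models(separable_rows(80), build_schema(), seed = 3)
  ev <- evaluate_models(bundle, rows2)
  expect_true(is.na(ev$record_pearson))
  expect_error(evaluate_models(bundle, rows2[0, ]), "empty")
})

test_that("signal-bearing synthetic validation data is well predicted", {
  u <- generate_synthetic_chembl(synthetic_config(seed = 404,
                                                  n_compounds = 600))
  res <- run_pipeline(u, seed = 31)
  ev <- res$evaluation
  expect_gt(ev$record_pearson, 0.6)
  expect_gt(ev$accuracy, 0.8)
  # countRatio separates the true labels (Fig. 4 left-panel analogue)
  crl <- ev$count_ratio_by_label
  expect_gt(crl$mean_count_ratio[crl$true_label == "active"],
            crl$mean_count_ratio[crl$true_label == "inactive"])
})
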