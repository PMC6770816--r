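# Random-forest classification (active/inactive) and regression (activity
# score) over the validation set, with per-compound aggregation: countRatio,
# the fraction of a compound's scored records the classifier calls active,
# and the mean regression prediction.

#' @importFrom ranger ranger
NULL

.feature_matrix <- function(rows, schema) {
  m <- as.data.frame(rows[schema$name])
  stopifnot(ncol(m) == nrow(schema))
  m
}

#' Split a validation set 80/20 at the record level
#'
#' @param rows Encoded validation rows.
#' @param seed Integer seed; the partition is reproducible under it.
#' @param fraction Training fraction, strictly inside (0, 1); default 0.8.
#' @return A list of class `mel_split` with `seed`, `fraction`,
#'   `train_record_ids`, `test_record_ids` (disjoint, jointly exhaustive).
#' @export
split_rows <- function(rows, seed, fraction = 0.8) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly between 0 and 1")
  }
  if (nrow(rows) < 5L) stop("at least 5 rows are required to split")
  ids <- rows$record_id
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  train <- withr::with_seed(seed, sample(ids, n_train))
  structure(
    list(seed = seed, fraction = fraction,
         train_record_ids = sort(train),
         test_record_ids = sort(setdiff(ids, train))),
    class = "mel_split"
  )
}

#' Train the classification and regression forests
#'
#' Fits a random-forest classifier on the activity label and a
#' random-forest regressor on the activity score, over the same feature
#' schema. Defaults: 100 trees, unlimited depth, sqrt(p) candidate features
#' per split for classification and p/3 for regression, single thread for
#' reproducibility.
#'
#' @param train_rows Encoded training rows (both labels must be present).
#' @param schema Feature schema in force.
#' @param seed Mandatory integer seed, stored in the bundle.
#' @param num_trees Number of trees (default 100).
#' @return A list of class `mel_bundle`: `classifier`, `regressor`,
#'   `schema_fingerprint`, `hyperparameters`, `seed`, `training_metrics`.
#' @export
train_models <- function(train_rows, schema, seed, num_trees = 100L) {
  if (length(unique(train_rows$label)) < 2L) {
    stop("training data carries a single class; both labels are required")
  }
  x <- .feature_matrix(train_rows, schema)
  p <- ncol(x)
  mtry_cls <- max(1L, floor(sqrt(p)))
  mtry_reg <- max(1L, floor(p / 3))

  cls_data <- cbind(x, .label = factor(train_rows$label,
                                       levels = c("inactive", "active")))
  classifier <- ranger::ranger(
    dependent.variable.name = ".label", data = cls_data,
    num.trees = num_trees, mtry = mtry_cls, seed = seed, num.threads = 1,
    respect.unordered.factors = "ignore"
  )
  reg_data <- cbind(x, .score = train_rows$activity_score)
  regressor <- ranger::ranger(
    dependent.variable.name = ".score", data = reg_data,
    num.trees = num_trees, mtry = mtry_reg, seed = seed, num.threads = 1
  )
  structure(
    list(
      classifier = classifier,
      regressor = regressor,
      schema = schema,
      schema_fingerprint = schema_fingerprint(schema),
      hyperparameters = list(num_trees = num_trees, mtry_classification =
                               mtry_cls, mtry_regression = mtry_reg),
      seed = seed,
      training_metrics = list(
        oob_classification_error = classifier$prediction.error,
        oob_regression_mse = regressor$prediction.error
      )
    ),
    class = "mel_bundle"
  )
}

#' Score rows with a trained bundle
#'
#' Emits one class call and one regression score per row. Any label or
#' activity-score column present in `rows` is ignored: only the schema
#' features enter the models.
#'
#' @param bundle From [train_models()].
#' @param rows Encoded rows under the same schema.
#' @return Tibble: `record_id`, `compound_id`, `call`
#'   (`active`/`inactive`), `predicted_score`.
#' @export
predict_records <- function(bundle, rows) {
  fp <- attr(rows, "schema_fingerprint")
  if (!is.null(fp) && !identical(fp, bundle$schema_fingerprint)) {
    stop("rows were encoded under a different schema than the bundle")
  }
  x <- .feature_matrix(rows, bundle$schema)
  call <- as.character(stats::predict(bundle$classifier, data = x,
                                      num.threads = 1)$predictions)
  score <- stats::predict(bundle$regressor, data = x,
                          num.threads = 1)$predictions
  tibble::tibble(
    record_id = rows$record_id,
    compound_id = rows$compound_id,
    call = call,
    predicted_score = score
  )
}

#' Aggregate per-record predictions to compounds
#'
#' Per compound: the number of scored occasions, the number of active
#' calls, their ratio (countRatio), the mean predicted score, and the
#' actual averaged score when one exists.
#'
#' @param predictions From [predict_records()].
#' @param actuals Optional tibble with `compound_id`, `average_score`.
#' @return Tibble: `compound_id`, `n_occasions`, `n_active_calls`,
#'   `count_ratio`, `mean_predicted_score`, `actual_score`.
#' @export
aggregate_compound <- function(predictions, actuals = NULL) {
  out <- predictions %>%
    dplyr::group_by(.data$compound_id) %>%
    dplyr::summarise(
      n_occasions = dplyr::n(),
      n_active_calls = sum(.data$call == "active"),
      mean_predicted_score = mean(.data$predicted_score),
      .groups = "drop"
    ) %>%
    dplyr::mutate(count_ratio = .data$n_active_calls / .data$n_occasions)
  if (!is.null(actuals)) {
    out$actual_score <- actuals$average_score[
      match(out$compound_id, actuals$compound_id)]
  } else {
    out$actual_score <- NA_real_
  }
  out[, c("compound_id", "n_occasions", "n_active_calls", "count_ratio",
          "mean_predicted_score", "actual_score")]
}

#' Evaluate a bundle on held-out rows
#'
#' The held-back truth (label and activity score) is compared with the
#' model outputs: regression Pearson/Spearman correlation per record and
#' per compound, the classification confusion matrix, and the countRatio
#' distribution stratified by true compound label.
#'
#' @param bundle From [train_models()].
#' @param test_rows Encoded rows carrying `label` and `activity_score`.
#' @return A list of class `mel_evaluation`.
#' @export
evaluate_models <- function(bundle, test_rows) {
  if (nrow(test_rows) == 0L) stop("empty test set")
  pred <- predict_records(bundle, test_rows)

  safe_cor <- function(x, y, method) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y, method = method)
  }
  rec_pearson <- safe_cor(pred$predicted_score, test_rows$activity_score,
                          "pearson")
  rec_spearman <- safe_cor(pred$predicted_score, test_rows$activity_score,
                           "spearman")

  confusion <- table(
    truth = factor(test_rows$label, levels = c("inactive", "active")),
    call = factor(pred$call, levels = c("inactive", "active"))
  )

  truth_by_compound <- test_rows %>%
    dplyr::group_by(.data$compound_id) %>%
    dplyr::summarise(actual_score = mean(.data$activity_score),
                     true_label = .data$label[1], .groups = "drop")
  agg <- aggregate_compound(
    pred,
    tibble::tibble(compound_id = truth_by_compound$compound_id,
                   average_score = truth_by_compound$actual_score)
  )
  agg$true_label <- truth_by_compound$true_label[
    match(agg$compound_id, truth_by_compound$compound_id)]

  cmp_pearson <- safe_cor(agg$mean_predicted_score, agg$actual_score,
                          "pearson")
  cmp_spearman <- safe_cor(agg$mean_predicted_score, agg$actual_score,
                           "spearman")
  count_ratio_by_label <- agg %>%
    dplyr::group_by(.data$true_label) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_count_ratio = mean(.data$count_ratio),
      median_count_ratio = stats::median(.data$count_ratio),
      .groups = "drop"
    )
  structure(
    list(
      n_records = nrow(test_rows),
      record_pearson = rec_pearson,
      record_spearman = rec_spearman,
      compound_pearson = cmp_pearson,
      compound_spearman = cmp_spearman,
      confusion = confusion,
      accuracy = sum(diag(confusion)) / sum(confusion),
      count_ratio_by_label = count_ratio_by_label,
      compound_predictions = agg
    ),
    class = "mel_evaluation"
  )
}

#' @export
print.mel_evaluation <- function(x, ...) {
  cat("Model evaluation on", x$n_records, "held-out records\n")
  cat("  regression r (record):  ",
      formatC(x$record_pearson, digits = 3, format = "f"),
      " (Spearman ", formatC(x$record_spearman, digits = 3, format = "f"),
      ")\n", sep = "")
  cat("  regression r (compound):",
      formatC(x$compound_pearson, digits = 3, format = "f"), "\n")
  cat("  classification accuracy:",
      formatC(x$accuracy, digits = 3, format = "f"), "\n")
  print(x$confusion)
  invisible(x)
}

#' Persist a model bundle with a JSON metadata sidecar
#'
#' @param bundle From [train_models()].
#' @param path Path for the serialized bundle (RDS); metadata lands in
#'   `<path>.json`.
#' @export
write_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  meta <- list(
    seed = bundle$seed,
    hyperparameters = bundle$hyperparameters,
    schema_fingerprint = bundle$schema_fingerprint,
    training_metrics = bundle$training_metrics
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
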