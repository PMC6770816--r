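# End-to-end pipeline: tables -> potency scores -> subtype averages ->
# 60-variable validation set -> negative augmentation -> 80/20 split ->
# random forests -> database-wide screen -> cardiovascular cross-filter.

#' Run the full screening pipeline
#'
#' Orchestrates every stage over a set of activity/compound/assay tables
#' (typically from [generate_synthetic_chembl()]). The validation set
#' comprises every record of the melatonin-related compounds (those with at
#' least one scorable melatonin receptor record) plus one artificial
#' inactive row per sampled GPCR-inactive compound. The trained bundle then
#' screens the whole record universe and the hits are cross-filtered
#' against cardiovascular assays.
#'
#' @param tables List with `activities`, `compounds`, `assays` (and
#'   optionally `truth`).
#' @param seed Integer seed driving the split, training, and negative
#'   sampling.
#' @param label_threshold Activity label/hit threshold (default 4).
#' @param chembl_threshold Cardiovascular assay score threshold
#'   (default 4.5).
#' @param augment_count Number of artificial inactives; `NULL` (default)
#'   uses the published-ratio count capped at the eligible pool.
#' @param num_trees Trees per forest (default 100).
#' @param output_dir If non-NULL, deterministic TSV/JSON outputs are
#'   written there.
#' @return A list with every intermediate product: `scores`, `averages`,
#'   `subtype_cor`, `schema`, `validation`, `split`, `bundle`,
#'   `evaluation`, `screen_results`, `histogram`, `named_hits`, `cv`,
#'   `graph`, `truth_metrics` (when truth is present).
#' @export
run_pipeline <- function(tables, seed, label_threshold = 4,
                         chembl_threshold = 4.5, augment_count = NULL,
                         num_trees = 100L, output_dir = NULL) {
  records <- tables$activities
  compounds <- tables$compounds
  assays <- tables$assays

  linked <- link_tables(records, compounds, assays)
  view <- linked$view

  has_structure <- !is.na(compounds$smiles) & compounds$smiles != ""
  descriptors <- NULL
  mw <- NULL
  if (any(has_structure)) {
    descriptors <- compute_descriptors(
      unique(compounds$smiles[has_structure]))
    mw <- stats::setNames(
      descriptors$molecular_weight[match(compounds$smiles,
                                         descriptors$smiles)],
      compounds$compound_id
    )
  }

  scores <- suppressWarnings(potency_score(records, mw = mw))
  subtype_ids <- melatonin_subtype_ids(scores$target_id)
  if (length(subtype_ids) == 0) {
    stop("no melatonin receptor subtype records found")
  }
  means <- subtype_means(scores, subtype_ids)
  averages <- aggregate_subtypes(scores, subtype_ids)
  subtype_cor <- if (length(unique(means$target_id)) >= 2) {
    subtype_correlation(means)
  } else {
    NULL
  }

  schema <- build_schema()
  encoded <- encode_rows(view, schema, averages,
                         label_threshold = label_threshold,
                         descriptors = descriptors)

  # melatonin-related compounds: anything with a scorable subtype record
  mel_compounds <- unique(c(
    averages$compound_id,
    scores$compound_id[scores$target_id %in% subtype_ids]
  ))
  base_rows <- encoded[encoded$compound_id %in% mel_compounds, ,
                       drop = FALSE]
  attr(base_rows, "schema_fingerprint") <- attr(encoded,
                                                "schema_fingerprint")
  attr(base_rows, "label_threshold") <- label_threshold

  eligible <- find_inactives(records, assays, scores = scores,
                             score_threshold = label_threshold)
  eligible <- eligible[!eligible$compound_id %in% mel_compounds, ,
                       drop = FALSE]
  n_pool <- sum(eligible$eligible)
  if (is.null(augment_count)) {
    augment_count <- min(n_pool,
                         default_augment_count(length(mel_compounds)))
  }
  validation <- augment(base_rows, eligible, view, schema,
                        target_count = augment_count, seed = seed)

  split <- split_rows(validation, seed = seed)
  train_rows <- validation[validation$record_id %in%
                             split$train_record_ids, , drop = FALSE]
  test_rows <- validation[validation$record_id %in%
                            split$test_record_ids, , drop = FALSE]
  attr(train_rows, "schema_fingerprint") <-
    attr(validation, "schema_fingerprint")
  attr(test_rows, "schema_fingerprint") <-
    attr(validation, "schema_fingerprint")

  bundle <- train_models(train_rows, schema, seed = seed,
                         num_trees = num_trees)
  evaluation <- evaluate_models(bundle, test_rows)

  screen_results <- screen(bundle, encoded, averages,
                           hit_threshold = label_threshold)
  histogram <- score_histogram(screen_results)
  named_hits <- named_drug_hits(screen_results, compounds)

  flagged <- flag_cardiovascular(assays)
  coverage <- view %>%
    dplyr::distinct(.data$assay_id, .data$compound_id) %>%
    dplyr::count(.data$assay_id, name = "n_molecules_seen")
  flagged <- dplyr::left_join(flagged, coverage, by = "assay_id")
  cv <- select_cv_hits(screen_results, scores, flagged,
                       compounds = compounds,
                       chembl_threshold = chembl_threshold,
                       melatonin_threshold = label_threshold)
  graph <- if (nrow(cv$hits) > 0) interaction_graph(cv$hits) else NULL

  truth_metrics <- if (!is.null(tables$truth)) {
    truth_report(tables$truth, screen_results, cv)
  } else {
    NULL
  }

  out <- list(
    scores = scores, averages = averages, subtype_cor = subtype_cor,
    schema = schema, validation = validation, split = split,
    bundle = bundle, evaluation = evaluation,
    screen_results = screen_results, histogram = histogram,
    named_hits = named_hits, eligible = eligible, cv = cv, graph = graph,
    truth_metrics = truth_metrics
  )
  if (!is.null(output_dir)) {
    write_pipeline_outputs(out, output_dir)
  }
  out
}

#' Write the pipeline's deterministic output tables
#'
#' TSV tables and JSON summaries only; identical runs produce
#' byte-identical files.
#'
#' @param result From [run_pipeline()].
#' @param output_dir Directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  write_score_table(result$scores, p("potency_scores.tsv"))
  readr::write_tsv(result$averages, p("subtype_averages.tsv"),
                   progress = FALSE)
  if (!is.null(result$subtype_cor)) {
    readr::write_tsv(result$subtype_cor, p("subtype_correlation.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(result$screen_results, p("screen_results.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(result$histogram, p("score_histogram.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$named_hits, p("named_drug_hits.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(result$eligible, p("eligible_inactives.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$cv$in_vivo, p("cv_hits_in_vivo.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(result$cv$in_vitro, p("cv_hits_in_vitro.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(result$cv$summary, p("cv_summary.tsv"),
                   progress = FALSE)
  if (!is.null(result$graph)) {
    write_interaction_graph(result$graph, p("interaction_graph.graphml"),
                            p("interaction_edges.tsv"))
  }
  jsonlite::write_json(
    list(
      n_validation_rows = nrow(result$validation),
      class_balance = as.list(table(result$validation$label)),
      evaluation = list(
        record_pearson = result$evaluation$record_pearson,
        record_spearman = result$evaluation$record_spearman,
        compound_pearson = result$evaluation$compound_pearson,
        accuracy = result$evaluation$accuracy
      ),
      n_hits = sum(result$screen_results$is_hit),
      n_named_hits = nrow(result$named_hits),
      cv_summary = as.list(result$cv$summary),
      truth_metrics = result$truth_metrics
    ),
    p("pipeline_summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(output_dir)
}
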