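# Artificial inactive population: the activity label needs a population of
# non-active records, which melatonin-focused data almost entirely lacks.
# Negatives are harvested as molecules with inactivity evidence in at least
# ten distinct GPCR-class assays and appended to the validation set as
# inactive-labelled rows.

#' Find compounds with broad GPCR inactivity evidence
#'
#' A record counts as inactive evidence when its `activity_comment`
#' contains "Not Active", when its potency score falls below
#' `score_threshold`, or when it is censored from above (relation `>`)
#' with a bound below the threshold. Evidence is counted over distinct
#' GPCR-class assays, not records; a compound is eligible at
#' `min_assays` (default 10) distinct assays.
#'
#' @param records Activity tibble.
#' @param assays Assay tibble with `target_class`.
#' @param scores Optional potency score tibble for the same records
#'   (computed with [potency_score()] if omitted).
#' @param score_threshold Potency score below which a measured record is
#'   inactive evidence (default 4).
#' @param min_assays Minimum distinct GPCR assays with evidence (default 10).
#' @return Tibble with `compound_id`, `n_gpcr_assays_inactive`, `eligible`.
#' @export
find_inactives <- function(records, assays, scores = NULL,
                           score_threshold = 4, min_assays = 10L) {
  gpcr_assays <- assays$assay_id[
    grepl("gpcr|g protein|7tm", tolower(ifelse(is.na(assays$target_class),
                                               "", assays$target_class)))]
  rec <- records[records$assay_id %in% gpcr_assays, , drop = FALSE]
  if (is.null(scores)) {
    scores <- suppressWarnings(potency_score(rec))
  }
  sc <- scores[scores$assay_id %in% gpcr_assays, , drop = FALSE]

  comment_flag <- grepl("not active", ifelse(is.na(rec$activity_comment), "",
                                             rec$activity_comment),
                        ignore.case = TRUE)
  ev_comment <- rec[comment_flag, c("compound_id", "assay_id")]

  # measured below threshold, or an above-censored bound already below it
  low <- sc$score < score_threshold & sc$censored != "at_least"
  ev_score <- sc[low, c("compound_id", "assay_id")]

  evidence <- dplyr::distinct(dplyr::bind_rows(ev_comment, ev_score))
  counts <- dplyr::count(evidence, .data$compound_id,
                         name = "n_gpcr_assays_inactive")
  counts$eligible <- counts$n_gpcr_assays_inactive >= min_assays
  tibble::as_tibble(counts)
}

#' Augment a validation set with artificial inactive rows
#'
#' Samples up to `target_count` eligible compounds (deterministically under
#' `seed`) and appends one inactive-labelled row per sampled compound,
#' encoded under the same schema from one of the compound's GPCR evidence
#' records, with the inactive placeholder activity score. Pre-existing rows
#' are never modified.
#'
#' @param validation_rows Encoded rows ([encode_rows()]).
#' @param eligible Eligibility tibble ([find_inactives()]).
#' @param view Joined record view (for the evidence records' features).
#' @param schema The feature schema in force.
#' @param target_count Number of inactive compounds to add.
#' @param seed Integer seed controlling the sample.
#' @param inactive_score Placeholder activity score (default 0).
#' @return The augmented tibble; attribute `n_augmented` carries the number
#'   of appended rows and `class_balance` the final label table.
#' @export
augment <- function(validation_rows, eligible, view, schema, target_count,
                    seed, inactive_score = 0) {
  stopifnot(target_count >= 0)
  fp <- attr(validation_rows, "schema_fingerprint")
  if (!is.null(fp) && !identical(fp, schema_fingerprint(schema))) {
    stop("validation rows were encoded under a different schema")
  }
  pool <- sort(eligible$compound_id[eligible$eligible])
  if (target_count > length(pool)) {
    warning("only ", length(pool), " eligible inactive compound(s) for a ",
            "target of ", target_count, "; using all")
    target_count <- length(pool)
  }
  if (target_count == 0) {
    out <- validation_rows
    attr(out, "n_augmented") <- 0L
    attr(out, "class_balance") <- table(out$label)
    return(out)
  }
  sampled <- withr::with_seed(seed, sort(sample(pool, target_count)))

  # one evidence record per sampled compound: the first of its records in
  # the view, preferring GPCR-class assays, deterministic in view order
  cand <- view[view$compound_id %in% sampled, , drop = FALSE]
  is_gpcr <- grepl("gpcr|g protein|7tm",
                   tolower(ifelse(is.na(cand$target_class), "",
                                  cand$target_class)))
  cand <- cand[order(!is_gpcr, match(cand$record_id, view$record_id)), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$compound_id), , drop = FALSE]

  empty_avg <- tibble::tibble(compound_id = character(),
                              average_score = numeric())
  thr <- attr(validation_rows, "label_threshold")
  if (is.null(thr)) thr <- 4
  new_rows <- encode_rows(cand, schema, empty_avg, label_threshold = thr,
                          inactive_score = inactive_score)
  new_rows$record_id <- paste0("NEG_", new_rows$record_id)
  new_rows$label <- "inactive"
  new_rows$activity_score <- inactive_score

  out <- dplyr::bind_rows(validation_rows, new_rows)
  attr(out, "schema_fingerprint") <- fp
  attr(out, "label_threshold") <- thr
  attr(out, "n_augmented") <- nrow(new_rows)
  attr(out, "class_balance") <- table(out$label)
  out
}

#' Default augmentation size preserving the published class ratio
#'
#' The published design added 60,000 artificial inactives against 1,617
#' melatonin-related molecules; at reduced scale the same ratio is kept.
#'
#' @param n_active_compounds Number of melatonin-related compounds in the
#'   current run.
#' @return Integer target count.
#' @export
default_augment_count <- function(n_active_compounds) {
  as.integer(round(60000 * n_active_compounds / 1617))
}
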