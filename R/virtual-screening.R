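# Database-wide screening: apply the trained bundle to every record,
# aggregate per compound, and assign the final melatonin score — the
# measured averaged potency score when one exists, otherwise a combination
# of countRatio and the regression prediction.

#' Combine countRatio with the predicted score
#'
#' The combination rule used when no measured score exists:
#' `count_ratio * mean_predicted_score`. The product damps compounds the
#' classifier calls active inconsistently while preserving the magnitude of
#' the regression output. Isolated here so an alternative rule can be
#' substituted in one place.
#'
#' @param count_ratio Fraction of a compound's records classified active.
#' @param mean_predicted_score Mean regression prediction.
#' @return Numeric combined score.
#' @export
combine_score <- function(count_ratio, mean_predicted_score) {
  count_ratio * mean_predicted_score
}

#' Screen a record universe
#'
#' Scores every record with the bundle (in batches), aggregates per
#' compound, and sets `melatonin_score` to the actual averaged potency
#' score when present, else to [combine_score()] of countRatio and the
#' mean predicted score. A compound is a hit when its melatonin score
#' strictly exceeds `hit_threshold`.
#'
#' @param bundle From [train_models()].
#' @param universe_rows Encoded rows for every record to screen.
#' @param actuals Tibble `compound_id`, `average_score` of measured
#'   averages ([aggregate_subtypes()]).
#' @param hit_threshold Strict threshold for hit calling (default 4).
#' @param batch_size Records scored per batch (default 10000).
#' @return Tibble of class results: `compound_id`, `count_ratio`,
#'   `mean_predicted_score`, `actual_score`, `melatonin_score`, `is_hit`,
#'   `n_records`.
#' @export
screen <- function(bundle, universe_rows, actuals, hit_threshold = 4,
                   batch_size = 10000L) {
  if (nrow(universe_rows) == 0L) stop("empty screening universe")
  starts <- seq(1L, nrow(universe_rows), by = batch_size)
  preds <- dplyr::bind_rows(lapply(starts, function(s) {
    e <- min(s + batch_size - 1L, nrow(universe_rows))
    predict_records(bundle, universe_rows[s:e, , drop = FALSE])
  }))
  agg <- aggregate_compound(preds, actuals)
  melatonin_score <- ifelse(
    is.na(agg$actual_score),
    combine_score(agg$count_ratio, agg$mean_predicted_score),
    agg$actual_score
  )
  tibble::tibble(
    compound_id = agg$compound_id,
    count_ratio = agg$count_ratio,
    mean_predicted_score = agg$mean_predicted_score,
    actual_score = agg$actual_score,
    melatonin_score = melatonin_score,
    is_hit = melatonin_score > hit_threshold,
    n_records = agg$n_occasions
  )
}

#' Histogram of melatonin scores
#'
#' @param results Screen results ([screen()]).
#' @param bin_width Positive bin width (default 0.25).
#' @return Tibble `bin_low`, `bin_high`, `count`; counts sum to the number
#'   of compounds screened.
#' @export
score_histogram <- function(results, bin_width = 0.25) {
  if (nrow(results) == 0L) stop("no screen results to bin")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive")
  }
  s <- results$melatonin_score
  lo <- floor(min(s) / bin_width) * bin_width
  hi <- ceiling(max(s) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(breaks) < max(s)) breaks <- c(breaks, max(breaks) + bin_width)
  h <- graphics::hist(s, breaks = breaks, plot = FALSE, right = FALSE)
  tibble::tibble(
    bin_low = h$breaks[-length(h$breaks)],
    bin_high = h$breaks[-1],
    count = h$counts
  )
}

#' Hits that carry a drug name
#'
#' Filters screen hits to compounds with a non-empty preferred name,
#' sorted by melatonin score descending.
#'
#' @param results Screen results.
#' @param compounds Compound tibble with `pref_name`.
#' @return Tibble of named hits with `pref_name` and `max_phase` attached.
#' @export
named_drug_hits <- function(results, compounds) {
  hits <- results[results$is_hit, , drop = FALSE]
  hits$pref_name <- compounds$pref_name[match(hits$compound_id,
                                              compounds$compound_id)]
  hits$max_phase <- compounds$max_phase[match(hits$compound_id,
                                              compounds$compound_id)]
  named <- hits[!is.na(hits$pref_name) & hits$pref_name != "", ,
                drop = FALSE]
  named[order(-named$melatonin_score), , drop = FALSE]
}
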