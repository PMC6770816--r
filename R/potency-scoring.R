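# Melatonin potency score: heterogeneous activity measurements normalized
# to -log10 of the active concentration in mol/L, so that 6 is 1 uM and 9
# is 1 nM, then averaged per compound across melatonin receptor subtypes.

.concentration_types <- c("IC50", "EC50", "Ki", "Kd", "AC50", "Potency")

# unit string -> multiplier taking standard_value to mol/L (ug/mL handled
# separately because it needs the molecular weight)
.unit_to_molar <- c(
  "nM" = 1e-9, "uM" = 1e-6, "mM" = 1e-3, "M" = 1
)

#' Transform activity records into potency scores
#'
#' Converts every concentration-typed record (IC50, EC50, Ki, Kd, AC50,
#' Potency) with convertible units into a potency score, the -log10 of the
#' measured concentration in mol/L. Mass-concentration units (ug/mL) are
#' converted through the compound's molecular weight when available.
#' Non-concentration types (percent inhibition and the like) yield no
#' score.
#' Records with relation `>` or `>=` are censored from above
#' (`censored = "at_most"`: the true score is at most the bound); `<` or
#' `<=` are censored from below (`"at_least"`).
#'
#' @param records Activity tibble ([read_activity_table()]).
#' @param mw Optional named numeric vector of molecular weights (g/mol) by
#'   `compound_id`, required only for ug/mL records.
#' @return Tibble with columns `record_id`, `compound_id`, `assay_id`,
#'   `target_id`, `score`, `censored` (`none`/`at_most`/`at_least`),
#'   `source_type`. Unconvertible records are omitted; their count is
#'   attached as attribute `n_unscored` and zero/negative values raise a
#'   warning.
#' @export
potency_score <- function(records, mw = NULL) {
  stopifnot(is.data.frame(records))
  type_ok <- records$standard_type %in% .concentration_types
  value <- records$standard_value
  units <- records$standard_units

  molar <- rep(NA_real_, nrow(records))
  known <- units %in% names(.unit_to_molar)
  molar[known] <- value[known] * .unit_to_molar[units[known]]

  is_mass <- !is.na(units) & units %in% c("ug/mL", "ug.mL-1", "ug ml-1")
  if (any(is_mass)) {
    w <- if (is.null(mw)) rep(NA_real_, nrow(records)) else
      unname(mw[records$compound_id])
    no_mw <- is_mass & is.na(w)
    if (any(no_mw & type_ok & !is.na(value))) {
      warning(sum(no_mw & type_ok & !is.na(value)),
              " ug/mL record(s) without molecular weight left unscored")
    }
    # value ug/mL = value * 1e-3 g/L; divide by MW g/mol for mol/L
    molar[is_mass] <- (value[is_mass] * 1e-3) / w[is_mass]
  }

  nonpos <- type_ok & !is.na(molar) & molar <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " record(s) with zero or negative value unscored")
    molar[nonpos] <- NA_real_
  }

  scorable <- type_ok & !is.na(molar)
  censored <- dplyr::case_when(
    records$standard_relation %in% c(">", ">=") ~ "at_most",
    records$standard_relation %in% c("<", "<=") ~ "at_least",
    TRUE ~ "none"
  )
  out <- tibble::tibble(
    record_id = records$record_id[scorable],
    compound_id = records$compound_id[scorable],
    assay_id = records$assay_id[scorable],
    target_id = records$target_id[scorable],
    score = -log10(molar[scorable]),
    censored = censored[scorable],
    source_type = records$standard_type[scorable]
  )
  attr(out, "n_unscored") <- sum(!scorable)
  out
}

#' Per-compound average potency across melatonin receptor subtypes
#'
#' Computes, per compound, the mean score within each melatonin receptor
#' subtype and then the unweighted mean across subtypes present, so that
#' heavily assayed subtypes do not dominate. Scores censored from above
#' (relation `>`) contribute no value to the average; they are inactivity
#' evidence only. Bound values from `<` relations are included.
#'
#' @param scores Potency score tibble ([potency_score()]).
#' @param subtype_ids Character vector of melatonin receptor target ids.
#' @return Tibble with `compound_id`, `average_score`, `n_records`,
#'   `n_subtypes`. Compounds without any usable subtype record are absent.
#' @export
aggregate_subtypes <- function(scores, subtype_ids) {
  stopifnot(length(subtype_ids) > 0)
  means <- subtype_means(scores, subtype_ids)
  means %>%
    dplyr::group_by(.data$compound_id) %>%
    dplyr::summarise(
      average_score = mean(.data$mean_score),
      n_records = sum(.data$n),
      n_subtypes = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-compound, per-subtype mean potency
#'
#' @inheritParams aggregate_subtypes
#' @return Tibble with `compound_id`, `target_id`, `mean_score`, `n`.
#' @export
subtype_means <- function(scores, subtype_ids) {
  scores %>%
    dplyr::filter(
      .data$target_id %in% subtype_ids,
      .data$censored != "at_most"
    ) %>%
    dplyr::group_by(.data$compound_id, .data$target_id) %>%
    dplyr::summarise(
      mean_score = mean(.data$score),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Correlation between receptor-subtype potency profiles
#'
#' Pearson and Spearman correlation of per-compound mean scores for every
#' pair of subtypes, over the compounds measured in both. Pairs with fewer
#' than three shared compounds report `NA` coefficients with the n.
#'
#' @param means Per-subtype mean tibble ([subtype_means()]).
#' @return Tibble with `subtype_a`, `subtype_b`, `n`, `pearson`, `spearman`.
#' @export
subtype_correlation <- function(means) {
  wide <- means %>%
    dplyr::select("compound_id", "target_id", "mean_score") %>%
    tidyr::pivot_wider(names_from = "target_id", values_from = "mean_score")
  subtypes <- setdiff(names(wide), "compound_id")
  pairs <- utils::combn(sort(subtypes), 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    x <- wide[[p[1]]]; y <- wide[[p[2]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n >= 3) {
      tibble::tibble(
        subtype_a = p[1], subtype_b = p[2], n = n,
        pearson = stats::cor(x[ok], y[ok], method = "pearson"),
        spearman = stats::cor(x[ok], y[ok], method = "spearman")
      )
    } else {
      tibble::tibble(subtype_a = p[1], subtype_b = p[2], n = n,
                     pearson = NA_real_, spearman = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}

#' Write a potency score table as TSV
#'
#' @param scores Potency score tibble.
#' @param path Output path.
#' @export
write_score_table <- function(scores, path) {
  cols <- c("compound_id", "target_id", "assay_id", "score", "censored",
            "source_type")
  readr::write_tsv(scores[cols], path, na = "", progress = FALSE)
  invisible(path)
}
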