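# Cardiovascular cross-filter: among screened melatonin-active compounds,
# find the records measured potent in cardiovascular assays, split into
# in-vivo and in-vitro tables, and build the compound-assay bipartite
# interaction graph.

#' Default cardiovascular keyword list
#'
#' Case-insensitive regular expressions matched against assay descriptions
#' and tissue annotations to flag an assay as cardiovascular. Stemmed terms
#' (`\\baort`, `\\batri`) cover the inflections (aorta/aortic,
#' atria/atrial/atrium) without matching unrelated words such as
#' "pediatric". Configurable and audited: the matched term is recorded per
#' assay.
#'
#' @return Character vector of keyword patterns.
#' @export
cv_keywords <- function() {
  c("heart", "cardiac", "\\baort", "coronary", "arrhythmi",
    "blood pressure", "hypertens", "vasoconstrict", "vasodilat",
    "\\batri", "ventric", "vascular")
}

#' Flag cardiovascular assays by keyword
#'
#' @param assays Assay tibble.
#' @param keywords Non-empty keyword list (default [cv_keywords()]).
#' @return `assays` with logical `is_cardiovascular` and `cv_matched_term`
#'   (the first keyword that matched, `NA` otherwise).
#' @export
flag_cardiovascular <- function(assays, keywords = cv_keywords()) {
  if (length(keywords) == 0L) stop("keyword list must not be empty")
  text <- paste(
    ifelse(is.na(assays$description), "", assays$description),
    ifelse(is.na(assays$tissue), "", assays$tissue)
  )
  matched <- rep(NA_character_, nrow(assays))
  for (kw in keywords) {
    hit <- is.na(matched) & grepl(kw, text, ignore.case = TRUE)
    matched[hit] <- kw
  }
  assays$is_cardiovascular <- !is.na(matched)
  assays$cv_matched_term <- matched
  assays
}

# in-vivo assays are recognized by whole-animal wording; everything else
# measured in preparations/cells counts as in vitro
.assay_category <- function(description, organism, cell_line) {
  desc <- tolower(ifelse(is.na(description), "", description))
  invivo <- grepl("in vivo|anesthetized|conscious|spontaneously hypertensive|\\brats?\\b.*\\b(iv|po|ip)\\b|whole animal", desc)
  ifelse(invivo, "in_vivo", "in_vitro")
}

#' Select cardiovascular hits
#'
#' One hit per activity record that passes all three conditions: the assay
#' is flagged cardiovascular, the measured potency score in that assay (the
#' ChEMBL score) strictly exceeds `chembl_threshold`, and the compound's
#' screen melatonin score strictly exceeds `melatonin_threshold`.
#'
#' @param results Screen results ([screen()]).
#' @param scores Per-record potency scores ([potency_score()]).
#' @param assays Assay tibble already passed through
#'   [flag_cardiovascular()], with `n_molecules_seen` if available.
#' @param compounds Optional compound tibble to attach `pref_name`.
#' @param chembl_threshold Strict bound on the in-assay score (default 4.5).
#' @param melatonin_threshold Strict bound on the screen score (default 4).
#' @return A list with `hits` (one row per passing record), `in_vivo` and
#'   `in_vitro` splits, and `summary` (distinct record/assay/molecule
#'   counts).
#' @export
select_cv_hits <- function(results, scores, assays, compounds = NULL,
                           chembl_threshold = 4.5,
                           melatonin_threshold = 4) {
  if (!"is_cardiovascular" %in% names(assays)) {
    stop("assays must be flagged with flag_cardiovascular() first")
  }
  cv_assays <- assays[assays$is_cardiovascular, , drop = FALSE]
  mel <- results[results$melatonin_score > melatonin_threshold, ,
                 drop = FALSE]

  hits <- scores[
    scores$assay_id %in% cv_assays$assay_id &
      scores$score > chembl_threshold &
      scores$compound_id %in% mel$compound_id, ,
    drop = FALSE
  ]
  idx_a <- match(hits$assay_id, cv_assays$assay_id)
  nms <- if ("n_molecules_seen" %in% names(cv_assays)) {
    cv_assays$n_molecules_seen[idx_a]
  } else {
    NA_integer_
  }
  out <- tibble::tibble(
    record_id = hits$record_id,
    compound_id = hits$compound_id,
    pref_name = if (is.null(compounds)) NA_character_ else
      compounds$pref_name[match(hits$compound_id, compounds$compound_id)],
    assay_id = hits$assay_id,
    assay_description = cv_assays$description[idx_a],
    assay_category = .assay_category(cv_assays$description[idx_a],
                                     cv_assays$organism[idx_a],
                                     cv_assays$cell_line[idx_a]),
    chembl_score = hits$score,
    melatonin_score = mel$melatonin_score[match(hits$compound_id,
                                                mel$compound_id)],
    n_molecules_seen = nms
  )
  list(
    hits = out,
    in_vivo = out[out$assay_category == "in_vivo", , drop = FALSE],
    in_vitro = out[out$assay_category == "in_vitro", , drop = FALSE],
    summary = tibble::tibble(
      n_records = dplyr::n_distinct(out$record_id),
      n_assays = dplyr::n_distinct(out$assay_id),
      n_molecules = dplyr::n_distinct(out$compound_id)
    )
  )
}

#' Compound-assay bipartite interaction graph
#'
#' Assay-model nodes on one side, molecule nodes on the other, one edge per
#' cardiovascular hit. Molecules with a preferred name carry it as label;
#' unnamed molecules (registry numbers only) are marked anonymous and their
#' label suppressed.
#'
#' @param cv_hits Hits tibble (`select_cv_hits()$hits`), non-empty.
#' @return An igraph graph with vertex attributes `type` (TRUE = molecule),
#'   `kind`, `label`, `anonymous`.
#' @export
interaction_graph <- function(cv_hits) {
  if (nrow(cv_hits) == 0L) stop("no cardiovascular hits to graph")
  edges <- dplyr::distinct(
    cv_hits[, c("compound_id", "assay_id", "pref_name")]
  )
  molecules <- dplyr::distinct(edges[, c("compound_id", "pref_name")])
  assays <- unique(edges$assay_id)
  g <- igraph::graph_from_data_frame(
    d = edges[, c("assay_id", "compound_id")],
    directed = FALSE,
    vertices = data.frame(
      name = c(assays, molecules$compound_id),
      kind = c(rep("assay_model", length(assays)),
               rep("molecule", nrow(molecules))),
      stringsAsFactors = FALSE
    )
  )
  named <- !is.na(molecules$pref_name) & molecules$pref_name != ""
  lab <- c(assays, ifelse(named, molecules$pref_name, ""))
  igraph::V(g)$label <- lab
  igraph::V(g)$anonymous <- c(rep(FALSE, length(assays)), !named)
  igraph::V(g)$type <- igraph::V(g)$kind == "molecule"
  g
}

#' Export the interaction graph
#'
#' @param graph From [interaction_graph()].
#' @param graphml_path Output GraphML path.
#' @param edgelist_path Optional TSV edge list path.
#' @export
write_interaction_graph <- function(graph, graphml_path,
                                    edgelist_path = NULL) {
  igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_edgelist(graph)
    readr::write_tsv(
      tibble::tibble(assay_id = el[, 1], compound_id = el[, 2]),
      edgelist_path, progress = FALSE
    )
  }
  invisible(graphml_path)
}
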