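#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# canonical (internal-dialect) column sets
.activity_cols <- c(
  "record_id", "compound_id", "assay_id", "target_id",
  "standard_type", "standard_relation", "standard_value", "standard_units",
  "activity_comment"
)
.compound_cols <- c("compound_id", "smiles", "pref_name", "max_phase")
.assay_cols <- c(
  "assay_id", "description", "assay_type", "target_class", "organism",
  "cell_line", "tissue", "bao_format"
)

# public ChEMBL CSV export header vocabulary -> internal names
.chembl_activity_map <- c(
  molecule_chembl_id = "compound_id",
  assay_chembl_id    = "assay_id",
  target_chembl_id   = "target_id",
  standard_type      = "standard_type",
  standard_relation  = "standard_relation",
  standard_value     = "standard_value",
  standard_units     = "standard_units",
  activity_comment   = "activity_comment"
)
.chembl_compound_map <- c(
  molecule_chembl_id = "compound_id",
  canonical_smiles   = "smiles",
  pref_name          = "pref_name",
  max_phase          = "max_phase"
)
.chembl_assay_map <- c(
  assay_chembl_id   = "assay_id",
  assay_description = "description",
  assay_type        = "assay_type",
  bao_format        = "bao_format",
  assay_organism    = "organism",
  assay_cell_type   = "cell_line",
  assay_tissue      = "tissue"
)

# comma/tab auto-detection on the header line, UTF-8 assumed
.detect_delim <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_comma <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_comma) "\t" else ","
}

.read_raw_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  readr::read_delim(
    path,
    delim = .detect_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = "UTF-8"),
    progress = FALSE,
    show_col_types = FALSE
  )
}

.require_columns <- function(tbl, cols, path) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0L) {
    stop(
      "missing mandatory column(s) in ", path, ": ",
      paste(missing, collapse = ", ")
    )
  }
}

.rename_by_map <- function(tbl, map) {
  keep <- intersect(names(map), names(tbl))
  out <- tbl[keep]
  names(out) <- unname(map[keep])
  out
}

#' Read a bioactivity record table
#'
#' Reads a ChEMBL-dialect or internal-dialect activity table from CSV/TSV
#' (delimiter auto-detected) into a tibble of activity records, one row per
#' experimental measurement. Rows lacking a compound or assay identifier are
#' dropped and counted; rows whose `standard_value` does not parse as a
#' number are retained with a missing value. Both counts are attached as
#' attributes (`n_malformed`, `n_value_unparseable`) and reported by warning,
#' never silently.
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect `"chembl_export"` for tables using the public ChEMBL CSV
#'   header vocabulary (`molecule_chembl_id`, `assay_chembl_id`, ...), or
#'   `"internal"` for the package's canonical column names.
#' @return A tibble with columns `record_id`, `compound_id`, `assay_id`,
#'   `target_id`, `standard_type`, `standard_relation`, `standard_value`
#'   (numeric), `standard_units`, `activity_comment`, in file row order.
#' @export
read_activity_table <- function(path, dialect = c("chembl_export", "internal")) {
  dialect <- match.arg(dialect)
  raw <- .read_raw_table(path)
  if (dialect == "chembl_export") {
    mandatory <- c("molecule_chembl_id", "assay_chembl_id", "standard_type",
                   "standard_value", "standard_units")
    .require_columns(raw, mandatory, path)
    tbl <- .rename_by_map(raw, .chembl_activity_map)
    if ("record_id" %in% names(raw)) tbl$record_id <- raw$record_id
  } else {
    .require_columns(raw, c("compound_id", "assay_id", "standard_type",
                            "standard_value", "standard_units"), path)
    tbl <- raw[intersect(.activity_cols, names(raw))]
  }
  for (col in .activity_cols) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  tbl <- tbl[.activity_cols]

  n_in <- nrow(tbl)
  keep <- !is.na(tbl$compound_id) & tbl$compound_id != "" &
    !is.na(tbl$assay_id) & tbl$assay_id != ""
  n_malformed <- sum(!keep)
  tbl <- tbl[keep, , drop = FALSE]

  raw_value <- tbl$standard_value
  value <- suppressWarnings(as.numeric(raw_value))
  unparseable <- !is.na(raw_value) & raw_value != "" & is.na(value)
  tbl$standard_value <- value

  # ChEMBL convention: absent relation means an exact value
  rel <- tbl$standard_relation
  rel[is.na(rel) | rel == ""] <- "="
  tbl$standard_relation <- rel

  if (any(is.na(tbl$record_id) | tbl$record_id == "")) {
    tbl$record_id <- sprintf("R%06d", seq_len(nrow(tbl)))
  }
  if (anyDuplicated(tbl$record_id)) {
    stop("record_id values are not unique in ", path)
  }
  if (any(!is.na(tbl$standard_value) & tbl$standard_value < 0)) {
    stop("negative standard_value encountered in ", path)
  }

  if (n_malformed > 0L) {
    warning(n_malformed, " malformed row(s) without compound/assay id dropped")
  }
  if (any(unparseable)) {
    warning(sum(unparseable), " row(s) with unparseable standard_value; ",
            "value set to missing")
  }
  out <- tibble::as_tibble(tbl)
  attr(out, "n_malformed") <- n_malformed
  attr(out, "n_value_unparseable") <- sum(unparseable)
  out
}

#' Read a compound table
#'
#' @inheritParams read_activity_table
#' @return A tibble with columns `compound_id`, `smiles`, `pref_name`,
#'   `max_phase` (integer 0-4).
#' @export
read_compound_table <- function(path, dialect = c("chembl_export", "internal")) {
  dialect <- match.arg(dialect)
  raw <- .read_raw_table(path)
  if (dialect == "chembl_export") {
    .require_columns(raw, c("molecule_chembl_id", "canonical_smiles"), path)
    tbl <- .rename_by_map(raw, .chembl_compound_map)
  } else {
    .require_columns(raw, c("compound_id", "smiles"), path)
    tbl <- raw[intersect(.compound_cols, names(raw))]
  }
  for (col in .compound_cols) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  tbl <- tbl[.compound_cols]
  tbl$max_phase <- suppressWarnings(as.integer(tbl$max_phase))
  tbl$max_phase[is.na(tbl$max_phase)] <- 0L
  if (any(!tbl$max_phase %in% 0:4)) stop("max_phase outside 0-4 in ", path)
  if (anyDuplicated(tbl$compound_id)) {
    stop("compound_id values are not unique in ", path)
  }
  tibble::as_tibble(tbl)
}

#' Read an assay table
#'
#' @inheritParams read_activity_table
#' @return A tibble with columns `assay_id`, `description`, `assay_type`,
#'   `target_class`, `organism`, `cell_line`, `tissue`, `bao_format`.
#' @export
read_assay_table <- function(path, dialect = c("chembl_export", "internal")) {
  dialect <- match.arg(dialect)
  raw <- .read_raw_table(path)
  if (dialect == "chembl_export") {
    .require_columns(raw, c("assay_chembl_id", "assay_description"), path)
    tbl <- .rename_by_map(raw, .chembl_assay_map)
    if ("target_class" %in% names(raw)) tbl$target_class <- raw$target_class
  } else {
    .require_columns(raw, c("assay_id", "description"), path)
    tbl <- raw[intersect(.assay_cols, names(raw))]
  }
  for (col in .assay_cols) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  tbl <- tbl[.assay_cols]
  if (anyDuplicated(tbl$assay_id)) {
    stop("assay_id values are not unique in ", path)
  }
  tibble::as_tibble(tbl)
}

#' Write a table in the internal dialect
#'
#' Tables are written as TSV with canonical column order so that a
#' read/write/read cycle is the identity and a second write is
#' byte-identical to the first.
#'
#' @param tbl A tibble as returned by the corresponding reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(tbl, path) {
  .write_internal(tbl, .activity_cols, path)
}

#' @rdname write_activity_table
#' @export
write_compound_table <- function(tbl, path) {
  .write_internal(tbl, .compound_cols, path)
}

#' @rdname write_activity_table
#' @export
write_assay_table <- function(tbl, path) {
  .write_internal(tbl, .assay_cols, path)
}

.write_internal <- function(tbl, cols, path) {
  for (col in cols) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA
  }
  readr::write_tsv(tbl[cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Join records with compound and assay annotations
#'
#' Annotates every activity record with its compound and assay profile.
#' Records referencing a compound or assay id absent from the profile tables
#' are reported as orphans, not dropped and not fatal. The assay coverage
#' count `n_molecules_seen` (distinct compounds with records in the assay)
#' is computed here.
#'
#' @param records Activity tibble from [read_activity_table()].
#' @param compounds Compound tibble from [read_compound_table()].
#' @param assays Assay tibble from [read_assay_table()].
#' @return A list with `view` (records left-joined to both profiles, row
#'   order preserved) and `orphans` (a tibble of record_id and which
#'   reference failed to resolve).
#' @export
link_tables <- function(records, compounds, assays) {
  coverage <- records %>%
    dplyr::distinct(.data$assay_id, .data$compound_id) %>%
    dplyr::count(.data$assay_id, name = "n_molecules_seen")
  assays <- dplyr::left_join(assays, coverage, by = "assay_id")
  assays$n_molecules_seen[is.na(assays$n_molecules_seen)] <- 0L

  view <- records %>%
    dplyr::left_join(compounds, by = "compound_id") %>%
    dplyr::left_join(assays, by = "assay_id")

  orphan_compound <- !records$compound_id %in% compounds$compound_id
  orphan_assay <- !records$assay_id %in% assays$assay_id
  orphans <- tibble::tibble(
    record_id = c(records$record_id[orphan_compound],
                  records$record_id[orphan_assay]),
    missing = c(rep("compound", sum(orphan_compound)),
                rep("assay", sum(orphan_assay)))
  )
  list(view = view, orphans = orphans)
}
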