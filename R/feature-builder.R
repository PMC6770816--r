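# The 60-variable validation-set encoding. Each activity record (one
# experimental fact) becomes one fixed-length feature vector spanning six
# variable families: chemical descriptors of the compound, assay properties,
# target properties, taxonomy, cell line/tissue, and enumerated bookkeeping
# variables. The published work states the families and the count but not
# the variable identities; this schema is the package's documented stand-in.

.schema_chemical <- c(
  "molecular_weight", "qed_weighted", "alogp", "molar_refractivity", "tpsa",
  "hbd", "hba", "rotatable_bonds", "aromatic_rings", "heavy_atoms",
  "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur", "n_fluorine",
  "n_halogen", "n_hetero", "n_alerts", "mw_per_heavy_atom", "hetero_fraction"
)
.schema_assay_types <- c("B", "F", "A", "P", "U")
.schema_assay_kw <- c("binding", "inhibition", "agonist", "antagonist",
                      "radioligand", "displacement", "cell", "functional")
.schema_assay <- c(
  paste0("assay_type_", c("binding", "functional", "admet", "physchem",
                          "other")),
  "bao_format_enc",
  paste0("kw_", .schema_assay_kw)
)
.schema_target <- c(
  "target_id_enc", "target_class_enc", "is_gpcr", "is_melatonin_receptor",
  "is_mtr1a", "is_mtr1b", "is_mtr1c", "has_target", "is_ion_channel",
  "is_enzyme"
)
.schema_taxonomy <- c(
  "organism_enc", "is_human", "is_rat", "is_mouse", "is_mammal",
  "has_organism"
)
.schema_cell_tissue <- c(
  "cell_line_enc", "has_cell_line", "tissue_enc", "has_tissue",
  "is_cardio_tissue", "is_neuro_tissue"
)
.schema_enumerated <- c(
  "standard_type_enc", "standard_relation_enc", "standard_units_enc",
  "assay_n_molecules_seen"
)

#' Feature schema configuration
#'
#' @param n_expected Total number of variables the schema must contain.
#'   Anything other than the sum of the built-in family sizes is rejected
#'   by [build_schema()]; the pipeline's feature vector is fixed at 60.
#' @return A config list.
#' @export
schema_config <- function(n_expected = 60L) {
  list(n_expected = as.integer(n_expected))
}

#' Build the 60-variable feature schema
#'
#' Deterministic ordered schema of exactly 60 variables: 20 chemical
#' descriptors, 14 assay variables, 10 target variables, 6 taxonomy, 6 cell
#' line/tissue, 4 enumerated bookkeeping variables.
#'
#' @param config From [schema_config()].
#' @return Tibble with columns `name`, `family`, `kind`, 60 rows.
#' @export
build_schema <- function(config = schema_config()) {
  fam <- list(
    chemical = .schema_chemical,
    assay = .schema_assay,
    target = .schema_target,
    taxonomy = .schema_taxonomy,
    cell_line_tissue = .schema_cell_tissue,
    enumerated = .schema_enumerated
  )
  schema <- dplyr::bind_rows(lapply(names(fam), function(f) {
    tibble::tibble(name = fam[[f]], family = f)
  }))
  schema$kind <- ifelse(grepl("_enc$", schema$name), "categorical-encoded",
                        "numeric")
  if (nrow(schema) != config$n_expected) {
    stop("schema holds ", nrow(schema), " variables but config requires ",
         config$n_expected)
  }
  if (anyDuplicated(schema$name)) stop("duplicate schema variable names")
  schema
}

#' Fingerprint of a schema
#'
#' Stable hash of the ordered variable names; model bundles refuse to score
#' rows encoded under a different schema.
#'
#' @param schema From [build_schema()].
#' @return Character scalar.
#' @export
schema_fingerprint <- function(schema) {
  rlang::hash(paste(schema$name, collapse = "|"))
}

# deterministic integer code per categorical value: a stable hash of the
# value itself, so the code never depends on which other values are present
# and rows encoded in different batches stay consistent; NA/"" -> -1
.dict_encode <- function(x) {
  x[is.na(x)] <- ""
  vals <- unique(x)
  codes <- vapply(vals, function(v) {
    if (v == "") return(-1L)
    strtoi(substr(rlang::hash(v), 1, 6), 16L)
  }, integer(1))
  unname(codes[match(x, vals)])
}

.kw_flag <- function(text, kw) {
  as.integer(grepl(kw, text, ignore.case = TRUE))
}

#' Encode activity records as validation-set rows
#'
#' One row per record in the joined view, with exactly the 60 features of
#' the schema, a categorical activity label and the activity score. The
#' label is `active` iff the compound's averaged melatonin potency score
#' strictly exceeds `label_threshold`; compounds without a measured average
#' are labelled `inactive` with activity score `inactive_score`. Categorical
#' variables are integer encoded by a stable hash of the value, so codes
#' stay consistent across encoding batches; missing numeric chemical
#' features are imputed with the column median and missing categoricals
#' with the sentinel -1.
#'
#' @param view Joined record view ([link_tables()]`$view`).
#' @param schema From [build_schema()].
#' @param averages Per-compound averages ([aggregate_subtypes()]).
#' @param label_threshold Potency score above which a compound is labelled
#'   active (default 4: 100 uM on the -log10 molar scale).
#' @param inactive_score Activity score assigned to rows of compounds with
#'   no measured average (default 0).
#' @param descriptors Optional precomputed [compute_descriptors()] table
#'   (with a `smiles` column) to avoid recomputation.
#' @return Tibble: `record_id`, `compound_id`, the 60 feature columns,
#'   `label`, `activity_score`; attribute `schema_fingerprint`.
#' @export
encode_rows <- function(view, schema, averages, label_threshold = 4,
                        inactive_score = 0, descriptors = NULL) {
  stopifnot(nrow(schema) == 60L)

  smiles <- view$smiles
  has_structure <- !is.na(smiles) & smiles != ""
  if (any(has_structure)) {
    if (is.null(descriptors)) {
      descriptors <- compute_descriptors(unique(smiles[has_structure]))
    }
    chem <- descriptors[match(smiles, descriptors$smiles), , drop = FALSE]
  } else {
    warning("no compound in the view carries a structure; ",
            "chemical features are all imputed")
    chem <- tibble::as_tibble(
      stats::setNames(
        rep(list(rep(NA_real_, nrow(view))), length(.schema_chemical) + 1),
        c("smiles", .schema_chemical)
      )
    )
  }
  if (sum(!has_structure) > 0) {
    warning(sum(!has_structure),
            " record(s) of compounds without structure; ",
            "chemical features imputed")
  }

  feat <- tibble::tibble(.rows = nrow(view))
  for (col in .schema_chemical) {
    v <- chem[[col]]
    med <- stats::median(v, na.rm = TRUE)
    if (is.na(med)) med <- -1
    v[is.na(v)] <- med
    feat[[col]] <- v
  }

  atype <- toupper(substr(ifelse(is.na(view$assay_type), "U",
                                 view$assay_type), 1, 1))
  feat$assay_type_binding <- as.integer(atype == "B")
  feat$assay_type_functional <- as.integer(atype == "F")
  feat$assay_type_admet <- as.integer(atype == "A")
  feat$assay_type_physchem <- as.integer(atype == "P")
  feat$assay_type_other <- as.integer(!atype %in% c("B", "F", "A", "P"))
  feat$bao_format_enc <- .dict_encode(view$bao_format)
  desc <- ifelse(is.na(view$description), "", view$description)
  for (kw in .schema_assay_kw) {
    feat[[paste0("kw_", kw)]] <- .kw_flag(desc, kw)
  }

  tclass <- tolower(ifelse(is.na(view$target_class), "", view$target_class))
  tid <- ifelse(is.na(view$target_id), "", view$target_id)
  feat$target_id_enc <- .dict_encode(view$target_id)
  feat$target_class_enc <- .dict_encode(view$target_class)
  feat$is_gpcr <- as.integer(grepl("gpcr|g protein|7tm", tclass))
  mtr <- .melatonin_subtype_of(tid)
  feat$is_melatonin_receptor <- as.integer(!is.na(mtr))
  feat$is_mtr1a <- as.integer(!is.na(mtr) & mtr == "MTR1A")
  feat$is_mtr1b <- as.integer(!is.na(mtr) & mtr == "MTR1B")
  feat$is_mtr1c <- as.integer(!is.na(mtr) & mtr == "MTR1C")
  feat$has_target <- as.integer(tid != "")
  feat$is_ion_channel <- as.integer(grepl("ion channel", tclass))
  feat$is_enzyme <- as.integer(grepl("enzyme|kinase|protease", tclass))

  org <- tolower(ifelse(is.na(view$organism), "", view$organism))
  feat$organism_enc <- .dict_encode(view$organism)
  feat$is_human <- as.integer(grepl("homo sapiens|human", org))
  feat$is_rat <- as.integer(grepl("rattus|\\brat\\b", org))
  feat$is_mouse <- as.integer(grepl("mus musculus|mouse", org))
  feat$is_mammal <- as.integer(feat$is_human | feat$is_rat | feat$is_mouse |
                                 grepl("sus |oryctolagus|canis|bos ", org))
  feat$has_organism <- as.integer(org != "")

  cl <- ifelse(is.na(view$cell_line), "", view$cell_line)
  ts <- tolower(ifelse(is.na(view$tissue), "", view$tissue))
  feat$cell_line_enc <- .dict_encode(view$cell_line)
  feat$has_cell_line <- as.integer(cl != "")
  feat$tissue_enc <- .dict_encode(view$tissue)
  feat$has_tissue <- as.integer(ts != "")
  feat$is_cardio_tissue <- as.integer(
    grepl("heart|cardiac|aorta|vascular|artery|atri|ventric", ts))
  feat$is_neuro_tissue <- as.integer(grepl("brain|neuro|pineal|retina", ts))

  feat$standard_type_enc <- .dict_encode(view$standard_type)
  feat$standard_relation_enc <- .dict_encode(view$standard_relation)
  feat$standard_units_enc <- .dict_encode(view$standard_units)
  nms <- view$n_molecules_seen
  feat$assay_n_molecules_seen <- ifelse(is.na(nms), -1, nms)

  feat <- feat[schema$name]
  stopifnot(ncol(feat) == 60L)

  avg <- averages$average_score[match(view$compound_id,
                                      averages$compound_id)]
  activity_score <- ifelse(is.na(avg), inactive_score, avg)
  label <- ifelse(activity_score > label_threshold, "active", "inactive")

  out <- dplyr::bind_cols(
    tibble::tibble(record_id = view$record_id,
                   compound_id = view$compound_id),
    feat,
    tibble::tibble(label = label, activity_score = activity_score)
  )
  attr(out, "schema_fingerprint") <- schema_fingerprint(schema)
  attr(out, "label_threshold") <- label_threshold
  out
}

# melatonin receptor subtype from a target id of the form used throughout
# the package (ids containing MTR1A/MTNR1A etc.)
.melatonin_subtype_of <- function(target_id) {
  up <- toupper(target_id)
  dplyr::case_when(
    grepl("MTN?R1A", up) ~ "MTR1A",
    grepl("MTN?R1B", up) ~ "MTR1B",
    grepl("MTN?R1C|GPR50", up) ~ "MTR1C",
    TRUE ~ NA_character_
  )
}

#' Default melatonin receptor subtype target ids
#'
#' Ids matched by substring against the `target_id` column; covers the
#' three receptor subtype naming conventions (MTR1A/MTR1B/MTR1C,
#' MTNR1A/MTNR1B).
#'
#' @param target_ids Character vector of target ids present in the data.
#' @return The subset of `target_ids` that are melatonin receptor subtypes.
#' @export
melatonin_subtype_ids <- function(target_ids) {
  target_ids <- unique(target_ids[!is.na(target_ids)])
  target_ids[!is.na(.melatonin_subtype_of(target_ids))]
}

#' Persist a validation set with its schema sidecar
#'
#' @param rows Encoded rows ([encode_rows()]).
#' @param schema The schema used.
#' @param path TSV output path; a `.schema.json` sidecar is written next
#'   to it.
#' @export
write_validation_set <- function(rows, schema, path) {
  readr::write_tsv(rows, path, na = "", progress = FALSE)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    list(fingerprint = schema_fingerprint(schema),
         variables = schema),
    paste0(sidecar, ".schema.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
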