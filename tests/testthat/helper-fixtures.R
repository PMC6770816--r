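# Fixtures built in code: tiny activity/compound/assay tables and a small
# synthetic universe shared across test files.

toy_activity_tbl <- function() {
  tibble::tibble(
    record_id = c("R1", "R2", "R3"),
    compound_id = c("C1", "C1", "C2"),
    assay_id = c("A1", "A2", "A1"),
    target_id = c("MTR1A", "MTR1B", "MTR1A"),
    standard_type = c("IC50", "Ki", "IC50"),
    standard_relation = c("=", "=", ">"),
    standard_value = c(1000, 1, 10000),
    standard_units = c("nM", "nM", "nM"),
    activity_comment = c(NA, NA, "Not Active")
  )
}

toy_compound_tbl <- function() {
  tibble::tibble(
    compound_id = c("C1", "C2"),
    smiles = unname(reference_structures()[c("melatonin", "tasimelteon")]),
    pref_name = c("MELATONIN", NA),
    max_phase = c(4L, 0L)
  )
}

toy_assay_tbl <- function() {
  tibble::tibble(
    assay_id = c("A1", "A2"),
    description = c("Binding affinity at human melatonin receptor MTR1A",
                    "Agonist activity at MTR1B in functional assay"),
    assay_type = c("B", "F"),
    target_class = c("GPCR", "GPCR"),
    organism = c("Homo sapiens", "Rattus norvegicus"),
    cell_line = c("CHO", NA),
    tissue = c(NA, NA),
    bao_format = c("BAO_0000219", NA)
  )
}

# small universe reused where full default scale is not needed
small_universe <- function(seed = 101, n = 250) {
  generate_synthetic_chembl(synthetic_config(
    seed = seed, n_compounds = n,
    n_melatonin_assays_per_subtype = 6,
    n_gpcr_panel_assays = 25,
    n_cv_assays = 15
  ))
}

# deterministic linearly separable validation-style rows: the activity
# score is a noiseless function of one feature, all 60 schema columns
# present
separable_rows <- function(n = 200, seed = 1) {
  schema <- build_schema()
  withr::with_seed(seed, {
    feat <- as.data.frame(matrix(stats::runif(n * 60), n, 60))
    names(feat) <- schema$name
    score <- ifelse(feat$molecular_weight > 0.5, 7, 1)
    rows <- dplyr::bind_cols(
      tibble::tibble(record_id = sprintf("S%04d", seq_len(n)),
                     compound_id = sprintf("C%04d", seq_len(n))),
      tibble::as_tibble(feat),
      tibble::tibble(label = ifelse(score > 4, "active", "inactive"),
                     activity_score = score)
    )
  })
  attr(rows, "schema_fingerprint") <- schema_fingerprint(schema)
  rows
}
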