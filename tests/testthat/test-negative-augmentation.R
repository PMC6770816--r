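mk_gpcr_records <- function(compound, n_assays, n_per_assay = 1,
                            comment = "Not Active") {
  tibble::tibble(
    record_id = sprintf("%s_R%03d", compound,
                        seq_len(n_assays * n_per_assay)),
    compound_id = compound,
    assay_id = rep(sprintf("G%03d", seq_len(n_assays)), each = n_per_assay),
    target_id = NA_character_,
    standard_type = "Inhibition",
    standard_relation = "=",
    standard_value = NA_real_,
    standard_units = NA_character_,
    activity_comment = comment
  )
}

gpcr_assay_tbl <- function(n = 20) {
  tibble::tibble(
    assay_id = sprintf("G%03d", seq_len(n)),
    description = "Binding affinity at some receptor",
    assay_type = "B", target_class = "GPCR", organism = "Homo sapiens",
    cell_line = NA_character_, tissue = NA_character_,
    bao_format = NA_character_
  )
}

test_that("eligibility boundary sits at ten distinct GPCR assays", {
  recs <- dplyr::bind_rows(
    mk_gpcr_records("C10", 10),
    mk_gpcr_records("C9", 9)
  )
  ev <- find_inactives(recs, gpcr_assay_tbl())
  expect_true(ev$eligible[ev$compound_id == "C10"])
  expect_false(ev$eligible[ev$compound_id == "C9"])
})

test_that("evidence is counted over distinct assays, not records", {
  recs <- mk_gpcr_records("C6", 6, n_per_assay = 2)  # 12 records, 6 assays
  ev <- find_inactives(recs, gpcr_assay_tbl())
  expect_equal(ev$n_gpcr_assays_inactive, 6L)
  expect_false(ev$eligible)
})

test_that("low measured scores and above-censored bounds count as evidence", {
  recs <- tibble::tibble(
    record_id = sprintf("R%02d", 1:12),
    compound_id = "C1",
    assay_id = sprintf("G%03d", 1:12),
    target_id = NA_character_,
    standard_type = "IC50",
    standard_relation = c(rep("=", 6), rep(">", 6)),
    standard_value = 1e6,                    # 1 mM -> score 3
    standard_units = "nM",
    activity_comment = NA_character_
  )
  ev <- find_inactives(recs, gpcr_assay_tbl())
  expect_equal(ev$n_gpcr_assays_inactive, 12L)
  # potent measurements are not evidence
  recs$standard_value <- 1  # 1 nM -> score 9
  ev2 <- find_inactives(recs, gpcr_assay_tbl())
  expect_equal(nrow(ev2), 0L)
})

test_that("eligibility is monotone in added evidence", {
  recs <- mk_gpcr_records("C1", 12)
  ev <- find_inactives(recs, gpcr_assay_tbl())
  expect_true(ev$eligible)
  ev2 <- find_inactives(dplyr::bind_rows(recs, mk_gpcr_records("C1", 15)),
                        gpcr_assay_tbl())
  expect_true(ev2$eligible)
  expect_gte(ev2$n_gpcr_assays_inactive, ev$n_gpcr_assays_inactive)
})

aug_fixture <- function(n_eligible = 20) {
  compounds <- tibble::tibble(
    compound_id = c("ACT1", sprintf("N%03d", seq_len(n_eligible))),
    smiles = drug_structure_library()$smiles[seq_len(n_eligible + 1)],
    pref_name = NA_character_,
    max_phase = 0L
  )
  act <- toy_activity_tbl()[1:2, ]
  act$compound_id <- "ACT1"
  negs <- dplyr::bind_rows(lapply(sprintf("N%03d", seq_len(n_eligible)),
                                  mk_gpcr_records, n_assays = 11))
  records <- dplyr::bind_rows(act, negs)
  assays <- dplyr::bind_rows(toy_assay_tbl(), gpcr_assay_tbl(15))
  linked <- link_tables(records, compounds, assays)
  schema <- build_schema()
  averages <- tibble::tibble(compound_id = "ACT1", average_score = 7)
  rows <- encode_rows(linked$view[linked$view$compound_id == "ACT1", ],
                      schema, averages)
  eligible <- find_inactives(records, assays)
  list(rows = rows, eligible = eligible, view = linked$view,
       schema = schema)
}

test_that("augmentation with target zero leaves the set unchanged", {
  f <- aug_fixture(5)
  out <- augment(f$rows, f$eligible, f$view, f$schema, target_count = 0,
                 seed = 1)
  expect_equal(nrow(out), nrow(f$rows))
  expect_equal(attr(out, "n_augmented"), 0L)
})

test_that("augmentation is reproducible and leaves pre-existing rows intact", {
  f <- aug_fixture(20)
  a1 <- augment(f$rows, f$eligible, f$view, f$schema, target_count = 10,
                seed = 42)
  a2 <- augment(f$rows, f$eligible, f$view, f$schema, target_count = 10,
                seed = 42)
  expect_identical(a1$record_id, a2$record_id)
  expect_equal(attr(a1, "n_augmented"), 10L)
  expect_equal(a1[seq_len(nrow(f$rows)), names(f$rows)],
               tibble::as_tibble(f$rows), ignore_attr = TRUE)
  added <- a1[-seq_len(nrow(f$rows)), ]
  expect_true(all(added$label == "inactive"))
  expect_true(all(added$activity_score == 0))
  # a different seed samples a different subset
  a3 <- augment(f$rows, f$eligible, f$view, f$schema, target_count = 10,
                seed = 43)
  expect_false(identical(a1$compound_id, a3$compound_id))
})

test_that("a target above the eligible pool uses all and warns", {
  f <- aug_fixture(8)
  expect_warning(
    out <- augment(f$rows, f$eligible, f$view, f$schema,
                   target_count = 50, seed = 1),
    "eligible"
  )
  expect_equal(attr(out, "n_augmented"), 8L)
})

test_that("generator-planted eligibles land in the final inactive count", {
  u <- generate_synthetic_chembl(synthetic_config(
    seed = 17, n_compounds = 300, n_cv_assays = 0,
    gpcr_inactive_fraction = 1
  ))
  ev <- find_inactives(
    u$activities, u$assays,
    scores = suppressWarnings(potency_score(
      u$activities,
      mw = stats::setNames(u$truth$compounds$mw,
                           u$truth$compounds$compound_id)))
  )
  truth <- u$truth$compounds
  expect_setequal(ev$compound_id[ev$eligible],
                  truth$compound_id[truth$gpcr_eligible])
})
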