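mk_record <- function(type = "IC50", relation = "=", value = 1000,
                      units = "nM", compound = "C1", assay = "A1",
                      target = "MTR1A", id = "R1") {
  tibble::tibble(
    record_id = id, compound_id = compound, assay_id = assay,
    target_id = target, standard_type = type,
    standard_relation = relation, standard_value = value,
    standard_units = units, activity_comment = NA_character_
  )
}

test_that("molar anchors transform exactly", {
  expect_equal(potency_score(mk_record(value = 1000, units = "nM"))$score,
               6, tolerance = 1e-9)
  expect_equal(potency_score(mk_record(type = "Ki", value = 1,
                                       units = "nM"))$score,
               9, tolerance = 1e-9)
  expect_equal(potency_score(mk_record(value = 1, units = "M"))$score, 0,
               tolerance = 1e-12)
})

test_that("ug/mL converts through the molecular weight", {
  # oracle: 0.2328 ug/mL at 232.283 g/mol = 1.0022e-6 M
  s <- potency_score(mk_record(value = 0.2328, units = "ug/mL"),
                     mw = c(C1 = 232.283))
  expect_equal(s$score, 6.00, tolerance = 0.01)
  # ug/mL without a molecular weight yields no score plus a warning
  expect_warning(
    s2 <- potency_score(mk_record(value = 0.2328, units = "ug/mL")),
    "molecular weight"
  )
  expect_equal(nrow(s2), 0L)
})

test_that("non-concentration types yield no score", {
  s <- potency_score(mk_record(type = "Inhibition", value = 55,
                               units = "%"))
  expect_equal(nrow(s), 0L)
  expect_equal(attr(s, "n_unscored"), 1L)
})

test_that("zero or negative values are unscored with a warning", {
  expect_warning(s <- potency_score(mk_record(value = 0)), "zero or negative")
  expect_equal(nrow(s), 0L)
})

test_that("relations map to censoring directions", {
  s <- potency_score(dplyr::bind_rows(
    mk_record(relation = ">", id = "R1"),
    mk_record(relation = "<", id = "R2"),
    mk_record(relation = "~", id = "R3")
  ))
  expect_equal(s$censored, c("at_most", "at_least", "none"))
})

test_that("the same concentration in any unit yields identical scores", {
  withr::local_seed(77)
  n <- 1000
  score_true <- runif(n, 2, 9)
  mw <- runif(n, 150, 500)
  conc <- 10^(-score_true)
  ids <- sprintf("C%04d", seq_len(n))
  as_unit <- function(units, value) {
    tibble::tibble(
      record_id = paste0(units, seq_len(n)), compound_id = ids,
      assay_id = "A1", target_id = "MTR1A", standard_type = "IC50",
      standard_relation = "=", standard_value = value,
      standard_units = units, activity_comment = NA_character_
    )
  }
  s_nm <- potency_score(as_unit("nM", conc * 1e9))$score
  s_um <- potency_score(as_unit("uM", conc * 1e6))$score
  s_m  <- potency_score(as_unit("M", conc))$score
  s_ug <- potency_score(as_unit("ug/mL", conc * mw * 1e3),
                        mw = stats::setNames(mw, ids))$score
  expect_true(all(abs(s_nm - score_true) < 1e-9))
  expect_true(all(abs(s_um - s_nm) < 1e-9))
  expect_true(all(abs(s_m - s_nm) < 1e-9))
  expect_true(all(abs(s_ug - s_nm) < 1e-9))
})

test_that("lower concentration means strictly higher score", {
  v <- sort(runif(50, 1, 1e6), decreasing = TRUE)
  s <- potency_score(tibble::tibble(
    record_id = sprintf("R%02d", seq_along(v)), compound_id = "C1",
    assay_id = "A1", target_id = "T", standard_type = "IC50",
    standard_relation = "=", standard_value = v, standard_units = "nM",
    activity_comment = NA_character_
  ))
  expect_true(all(diff(s$score) > 0))
})

test_that("subtype averaging is mean-of-subtype-means", {
  sc <- tibble::tibble(
    record_id = sprintf("R%d", 1:4),
    compound_id = "C1",
    assay_id = "A1",
    target_id = c("MTR1A", "MTR1A", "MTR1B", "MTR1B"),
    score = c(6, 8, 8, 8),
    censored = "none",
    source_type = "IC50"
  )
  # subtype means are 7 and 8; pooled-record mean would be 7.5
  avg <- aggregate_subtypes(sc, c("MTR1A", "MTR1B"))
  expect_equal(avg$average_score, 7.5)
  expect_equal(avg$n_records, 4L)

  one_each <- aggregate_subtypes(sc[c(1, 3), ], c("MTR1A", "MTR1B"))
  expect_equal(one_each$average_score, 7)

  single <- aggregate_subtypes(
    tibble::tibble(record_id = "R1", compound_id = "C9", assay_id = "A1",
                   target_id = "MTR1B", score = 5.5, censored = "none",
                   source_type = "Ki"),
    c("MTR1A", "MTR1B"))
  expect_equal(single$average_score, 5.5)
})

test_that("above-censored scores are excluded from the average", {
  sc <- tibble::tibble(
    record_id = c("R1", "R2"), compound_id = "C1", assay_id = "A1",
    target_id = "MTR1A", score = c(6, 3),
    censored = c("none", "at_most"), source_type = "IC50"
  )
  avg <- aggregate_subtypes(sc, "MTR1A")
  expect_equal(avg$average_score, 6)
  expect_equal(avg$n_records, 1L)
})

test_that("average always lies between the subtype means", {
  withr::local_seed(42)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    subs <- c("MTR1A", "MTR1B", "MTR1C")[1:k]
    sc <- tibble::tibble(
      record_id = sprintf("R%02d", 1:(k * 3)),
      compound_id = "C1", assay_id = "A1",
      target_id = rep(subs, each = 3),
      score = runif(k * 3, 2, 9), censored = "none", source_type = "IC50"
    )
    m <- subtype_means(sc, subs)
    avg <- aggregate_subtypes(sc, subs)
    expect_gte(avg$average_score, min(m$mean_score) - 1e-12)
    expect_lte(avg$average_score, max(m$mean_score) + 1e-12)
  }
})

test_that("subtype correlation handles exact and degenerate cases", {
  m <- tibble::tibble(
    compound_id = rep(sprintf("C%d", 1:5), 2),
    target_id = rep(c("MTR1A", "MTR1B"), each = 5),
    mean_score = c(1:5, 1:5), n = 1L
  )
  ct <- subtype_correlation(m)
  expect_equal(ct$pearson, 1)
  expect_equal(ct$spearman, 1)

  m$mean_score[6:10] <- 5:1  # anti-ordered
  ct2 <- subtype_correlation(m)
  expect_equal(ct2$spearman, -1)

  ct3 <- subtype_correlation(m[c(1, 2, 6, 7), ])  # only 2 shared
  expect_equal(ct3$n, 2L)
  expect_true(is.na(ct3$pearson))
})

test_that("planted subtype correlation of 0.9 is recovered within the sampling bound", {
  u <- generate_synthetic_chembl(synthetic_config(
    seed = 303, n_compounds = 700, fraction_melatonin_active = 0.6,
    noise_sd = 0.1, n_melatonin_assays_per_subtype = 8,
    n_gpcr_panel_assays = 10, n_cv_assays = 0
  ))
  mw <- stats::setNames(u$truth$compounds$mw, u$truth$compounds$compound_id)
  sc <- suppressWarnings(potency_score(u$activities, mw = mw))
  m <- subtype_means(sc, c("MTR1A", "MTR1B", "MTR1C"))
  # restrict to true actives: one latent population, n >= 200 shared
  act <- u$truth$compounds$compound_id[u$truth$compounds$true_active]
  ct <- subtype_correlation(m[m$compound_id %in% act, ])
  expect_true(all(ct$n >= 200))
  expect_true(all(abs(ct$pearson - 0.9) < 0.06))
})
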