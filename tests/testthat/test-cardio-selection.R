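cv_assay_fixture <- function() {
  tibble::tibble(
    assay_id = c("CV1", "CV2", "NEU1"),
    description = c("Inhibition of rat aortic ring contraction",
                    "Effect on blood pressure in vivo in anesthetized rats",
                    "Binding affinity at 5-HT2C"),
    assay_type = "F", target_class = NA_character_,
    organism = "Rattus norvegicus", cell_line = NA_character_,
    tissue = NA_character_, bao_format = NA_character_
  )
}

test_that("keyword flagging matches substrings case-insensitively and audits the term", {
  flagged <- flag_cardiovascular(cv_assay_fixture())
  expect_equal(flagged$is_cardiovascular, c(TRUE, TRUE, FALSE))
  expect_equal(flagged$cv_matched_term[1], "\\baort")
  expect_true(is.na(flagged$cv_matched_term[3]))
  expect_error(flag_cardiovascular(cv_assay_fixture(), keywords = character(0)),
               "empty")
})

test_that("generator-planted cardiovascular assays are exactly recovered", {
  u <- generate_synthetic_chembl(synthetic_config(seed = 4,
                                                  n_compounds = 80,
                                                  n_cv_assays = 40))
  flagged <- flag_cardiovascular(u$assays)
  planted <- u$truth$assays$assay_id[u$truth$assays$category == "cv"]
  expect_setequal(flagged$assay_id[flagged$is_cardiovascular], planted)
  expect_equal(sum(flagged$is_cardiovascular), 40L)
})

cv_toy <- function() {
  # 6 records; 3 pass both thresholds, in 2 CV assays with 2 molecules
  scores <- tibble::tibble(
    record_id = sprintf("R%d", 1:6),
    compound_id = c("M1", "M1", "M2", "M2", "M3", "M1"),
    assay_id = c("CV1", "CV2", "CV1", "NEU1", "CV1", "CV1"),
    target_id = NA_character_,
    score = c(5.0, 4.6, 4.8, 9.0, 6.0, 4.5),
    censored = "none", source_type = "IC50"
  )
  results <- tibble::tibble(
    compound_id = c("M1", "M2", "M3"),
    count_ratio = 1, mean_predicted_score = 5,
    actual_score = NA_real_,
    melatonin_score = c(5, 4.5, 3.0),  # M3 fails the melatonin filter
    is_hit = c(TRUE, TRUE, FALSE), n_records = 2L
  )
  list(scores = scores, results = results,
       assays = flag_cardiovascular(cv_assay_fixture()))
}

test_that("cv hit selection matches the hand-enumerated toy fixture", {
  f <- cv_toy()
  cv <- select_cv_hits(f$results, f$scores, f$assays)
  # R1 (M1,CV1,5.0), R2 (M1,CV2,4.6), R3 (M2,CV1,4.8) pass;
  # R4 not CV, R5 melatonin filter, R6 score 4.5 not strict
  expect_setequal(cv$hits$record_id, c("R1", "R2", "R3"))
  expect_equal(cv$summary$n_records, 3L)
  expect_equal(cv$summary$n_assays, 2L)
  expect_equal(cv$summary$n_molecules, 2L)
  # boundary: chembl_score exactly 4.5 is excluded
  expect_false("R6" %in% cv$hits$record_id)
  # infinite thresholds empty the table
  cv_inf <- select_cv_hits(f$results, f$scores, f$assays,
                           chembl_threshold = Inf,
                           melatonin_threshold = Inf)
  expect_equal(nrow(cv_inf$hits), 0L)
  # in vivo / in vitro split follows the assay wording
  expect_equal(sort(unique(cv$hits$assay_category)),
               c("in_vitro", "in_vivo"))
  expect_equal(cv$hits$assay_category[cv$hits$assay_id == "CV2"],
               "in_vivo")
})

test_that("selection equals an exhaustive triple-loop filter on random tables", {
  withr::local_seed(23)
  assays <- flag_cardiovascular(cv_assay_fixture())
  for (i in 1:200) {
    n <- sample(5:100, 1)
    scores <- tibble::tibble(
      record_id = sprintf("R%03d", seq_len(n)),
      compound_id = sample(sprintf("M%d", 1:8), n, replace = TRUE),
      assay_id = sample(assays$assay_id, n, replace = TRUE),
      target_id = NA_character_,
      score = runif(n, 3, 7), censored = "none", source_type = "IC50"
    )
    results <- tibble::tibble(
      compound_id = sprintf("M%d", 1:8),
      count_ratio = 1, mean_predicted_score = 5, actual_score = NA_real_,
      melatonin_score = runif(8, 2, 6), is_hit = NA, n_records = 1L
    )
    results$is_hit <- results$melatonin_score > 4
    got <- sort(select_cv_hits(results, scores, assays)$hits$record_id)
    want <- character(0)
    for (r in seq_len(n)) {
      a_ok <- assays$is_cardiovascular[assays$assay_id ==
                                         scores$assay_id[r]]
      m_ok <- results$melatonin_score[results$compound_id ==
                                        scores$compound_id[r]] > 4
      if (a_ok && scores$score[r] > 4.5 && m_ok) {
        want <- c(want, scores$record_id[r])
      }
    }
    expect_identical(got, sort(want))
  }
})

test_that("record, assay, and molecule counts fall as thresholds rise", {
  u <- generate_synthetic_chembl(synthetic_config(seed = 606,
                                                  n_compounds = 400))
  res <- run_pipeline(u, seed = 44)
  flagged <- flag_cardiovascular(u$assays)
  prev <- c(Inf, Inf, Inf)
  for (thr in c(3, 4, 4.5, 5, 6)) {
    cv <- select_cv_hits(res$screen_results, res$scores, flagged,
                         chembl_threshold = thr)
    now <- unlist(cv$summary)
    expect_true(all(now <= prev))
    prev <- now
  }
  prev <- c(Inf, Inf, Inf)
  for (thr in c(2, 3, 4, 5)) {
    cv <- select_cv_hits(res$screen_results, res$scores, flagged,
                         melatonin_threshold = thr)
    now <- unlist(cv$summary)
    expect_true(all(now <= prev))
    prev <- now
  }
})

test_that("the interaction graph is bipartite with conserved counts", {
  f <- cv_toy()
  cv <- select_cv_hits(f$results, f$scores, f$assays,
                       compounds = tibble::tibble(
                         compound_id = c("M1", "M2"),
                         smiles = NA, pref_name = c("DRUG1", NA),
                         max_phase = 0L))
  g <- interaction_graph(cv$hits)
  # 2 molecules + 2 assays, 3 edges
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_true(igraph::is_bipartite(g))
  # handshake lemma
  expect_equal(sum(igraph::degree(g)), 2L * igraph::ecount(g))
  # no molecule-molecule or assay-assay edges
  el <- igraph::as_edgelist(g)
  kind <- igraph::V(g)$kind
  names(kind) <- igraph::V(g)$name
  expect_true(all(kind[el[, 1]] != kind[el[, 2]]))
  # named molecule labelled, unnamed anonymous
  v <- igraph::V(g)
  expect_equal(v$label[v$name == "M1"], "DRUG1")
  expect_true(v$anonymous[v$name == "M2"])
  expect_equal(v$label[v$name == "M2"], "")

  single <- interaction_graph(cv$hits[1, ])
  expect_equal(igraph::vcount(single), 2L)
  expect_equal(igraph::ecount(single), 1L)
})

test_that("graph export writes GraphML and an edge list", {
  f <- cv_toy()
  cv <- select_cv_hits(f$results, f$scores, f$assays)
  g <- interaction_graph(cv$hits)
  gml <- withr::local_tempfile(fileext = ".graphml")
  el <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_graph(g, gml, el)
  expect_true(file.exists(gml))
  expect_match(readLines(gml, n = 2)[2], "graphml", ignore.case = TRUE)
  edges <- readr::read_tsv(el, show_col_types = FALSE)
  expect_equal(nrow(edges), igraph::ecount(g))
})
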