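# Synthetic ChEMBL-emulating universe with known ground truth.
#
# Emulates the statistical structure the pipeline consumes: compounds with
# latent melatonin activity measured across three correlated receptor
# subtypes in heterogeneous units and measurement types, a GPCR panel
# carrying inactivity evidence for the negative population, and a set of
# cardiovascular assays in which a subset of melatonin-active compounds is
# also potent. Structures come from the bundled drug-like library so that
# chemical descriptors are computable and realistic.

#' Configuration for the synthetic universe
#'
#' Defaults define the miniature study conditions used throughout the
#' package: 2,000 compounds of which 30% are truly melatonin-active, three
#' receptor subtypes with latent potency correlation 0.9, measurement noise
#' 0.5 log units, a mixed nM/uM/ug-mL unit vocabulary, and cardiovascular
#' potency planted for a quarter of the actives.
#'
#' @param seed Mandatory integer seed.
#' @param n_compounds Number of compounds (default 2000).
#' @param fraction_melatonin_active Fraction of truly active compounds
#'   (default 0.3; the planted count is exact, `round(n * fraction)`).
#' @param subtype_correlation Latent potency correlation between receptor
#'   subtypes (default 0.9).
#' @param n_melatonin_assays_per_subtype Assays per subtype (default 10).
#' @param n_gpcr_panel_assays GPCR panel size (default 50).
#' @param n_cv_assays Cardiovascular assay count (default 40).
#' @param fraction_active_also_cv_potent Fraction of actives planted potent
#'   (score > 5) in cardiovascular assays (default 0.25).
#' @param noise_sd Measurement noise on the log-potency scale (default 0.5).
#' @param unit_mixture Named proportions for concentration units among
#'   scorable records (default nM 0.6, uM 0.3, ug/mL 0.1).
#' @param censored_fraction Probability that a weak measurement is reported
#'   as an above-bound (`>`) record (default 0.1).
#' @param percent_fraction Fraction of melatonin-assay records emitted as
#'   non-concentration percent-inhibition measurements (default 0.05).
#' @param gpcr_inactive_fraction Fraction of inactive compounds planted
#'   with GPCR panel inactivity evidence (default 0.9).
#' @param named_fraction Fraction of compounds carrying a drug name
#'   (default 0.15).
#' @param n_orphans Records referencing unknown compound ids, for join
#'   auditing (default 0).
#' @param structureless If TRUE, compounds carry no SMILES; incompatible
#'   with a positive ug/mL unit weight.
#' @return A validated config list of class `mel_syn_config`.
#' @export
synthetic_config <- function(seed,
                             n_compounds = 2000L,
                             fraction_melatonin_active = 0.3,
                             subtype_correlation = 0.9,
                             n_melatonin_assays_per_subtype = 10L,
                             n_gpcr_panel_assays = 50L,
                             n_cv_assays = 40L,
                             fraction_active_also_cv_potent = 0.25,
                             noise_sd = 0.5,
                             unit_mixture = c("nM" = 0.6, "uM" = 0.3,
                                              "ug/mL" = 0.1),
                             censored_fraction = 0.1,
                             percent_fraction = 0.05,
                             gpcr_inactive_fraction = 0.9,
                             named_fraction = 0.15,
                             n_orphans = 0L,
                             structureless = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  fracs <- c(fraction_melatonin_active, subtype_correlation,
             fraction_active_also_cv_potent, censored_fraction,
             percent_fraction, gpcr_inactive_fraction, named_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(n_compounds, n_melatonin_assays_per_subtype,
            n_gpcr_panel_assays, n_cv_assays, n_orphans) < 0)) {
    stop("counts must be non-negative")
  }
  if (abs(sum(unit_mixture) - 1) > 1e-8) {
    stop("unit_mixture proportions must sum to 1")
  }
  if (structureless && unit_mixture["ug/mL"] > 0) {
    stop("ug/mL records need molecular weights: incompatible with ",
         "structureless compounds")
  }
  structure(as.list(environment()), class = "mel_syn_config")
}

.subtypes <- c("MTR1A", "MTR1B", "MTR1C")

# draw latent subtype potencies: equicorrelated trivariate normal
.latent_matrix <- function(n, mean, sd, rho) {
  sigma <- matrix(rho, 3, 3); diag(sigma) <- 1
  z <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(sigma)
  mean + sd * z
}

# express a potency score as (value, units, mw-aware) concentration record
.score_to_value <- function(score, unit, mw) {
  conc <- 10^(-score)  # mol/L
  switch(unit,
         "nM" = conc * 1e9,
         "uM" = conc * 1e6,
         "M" = conc,
         "ug/mL" = conc * mw * 1e3)
}

#' Generate the synthetic universe
#'
#' Fully reproducible under the config seed: two calls with the same config
#' produce identical tables.
#'
#' @param config From [synthetic_config()].
#' @return A list: `activities`, `compounds`, `assays` (internal-dialect
#'   tibbles) and `truth` (list of `compounds` and `assays` ground-truth
#'   tibbles).
#' @export
generate_synthetic_chembl <- function(config) {
  stopifnot(inherits(config, "mel_syn_config"))
  withr::with_seed(config$seed, .generate_impl(config))
}

.generate_impl <- function(cfg) {
  lib <- drug_structure_library()
  n <- cfg$n_compounds

  struct_idx <- sample(nrow(lib), n, replace = TRUE)
  compounds <- tibble::tibble(
    compound_id = sprintf("SYN%05d", seq_len(n)),
    smiles = if (cfg$structureless) NA_character_ else lib$smiles[struct_idx],
    pref_name = NA_character_,
    max_phase = sample(0:4, n, replace = TRUE,
                       prob = c(0.70, 0.10, 0.08, 0.07, 0.05))
  )
  named <- sample(n, round(cfg$named_fraction * n))
  compounds$pref_name[named] <- toupper(lib$name[struct_idx[named]])

  mw <- if (cfg$structureless) rep(NA_real_, n) else {
    props <- ChemmineOB::prop_OB(.parse_mols(lib$smiles))
    w <- vapply(props$formula, .formula_weight, numeric(1),
                USE.NAMES = FALSE)
    w[struct_idx]
  }

  n_active <- round(cfg$fraction_melatonin_active * n)
  active_idx <- sample(n, n_active)
  true_active <- seq_len(n) %in% active_idx
  latent <- matrix(NA_real_, n, 3, dimnames = list(NULL, .subtypes))
  latent[active_idx, ] <- .latent_matrix(n_active, mean = 7, sd = 1,
                                         rho = cfg$subtype_correlation)
  latent[-active_idx, ] <- .latent_matrix(n - n_active, mean = 2, sd = 1,
                                          rho = cfg$subtype_correlation)

  assays <- .make_assays(cfg)
  mel_assays <- assays[assays$category == "melatonin_subtype", ]
  gpcr_assays <- assays[assays$category == "gpcr_panel", ]
  cv_assays <- assays[assays$category == "cv", ]

  units <- names(cfg$unit_mixture)
  draw_units <- function(k) {
    sample(units, k, replace = TRUE, prob = cfg$unit_mixture)
  }
  conc_types <- c("IC50", "Ki", "EC50", "Kd")

  rec <- list()
  # inactivity evidence ledger: GPCR-class assays (melatonin receptors
  # included) in which each compound's emitted record is inactive evidence
  evidence <- list()

  # melatonin receptor measurements
  measured <- if (nrow(mel_assays) > 0) {
    which(true_active | stats::runif(n) < 0.3)
  } else {
    integer(0)
  }
  for (i in measured) {
    k <- min(nrow(mel_assays),
             if (true_active[i]) 2 + stats::rpois(1, 4) else
               1 + stats::rpois(1, 1))
    rows <- mel_assays[sample(nrow(mel_assays), k), ]
    score <- latent[i, rows$target_id] + stats::rnorm(k, 0, cfg$noise_sd)
    as_percent <- stats::runif(k) < cfg$percent_fraction
    unit <- draw_units(k)
    value <- vapply(seq_len(k), function(j) {
      .score_to_value(score[j], unit[j], mw[i])
    }, numeric(1))
    censor <- !as_percent & score < 4 &
      stats::runif(k) < cfg$censored_fraction
    rec[[length(rec) + 1]] <- tibble::tibble(
      compound_id = compounds$compound_id[i],
      assay_id = rows$assay_id,
      target_id = rows$target_id,
      standard_type = ifelse(as_percent, "Inhibition",
                             sample(conc_types, k, replace = TRUE)),
      standard_relation = ifelse(censor, ">", "="),
      standard_value = ifelse(as_percent,
                              round(stats::runif(k, 0, 100), 1), value),
      standard_units = ifelse(as_percent, "%", unit),
      activity_comment = NA_character_
    )
    weak <- !as_percent & score < 4
    if (any(weak)) {
      evidence[[length(evidence) + 1]] <- tibble::tibble(
        compound_id = compounds$compound_id[i],
        assay_id = rows$assay_id[weak]
      )
    }
  }

  # GPCR panel inactivity evidence for the negative population
  inactive_pool <- which(!true_active)
  planted <- if (nrow(gpcr_assays) > 0) {
    sample(inactive_pool,
           round(cfg$gpcr_inactive_fraction * length(inactive_pool)))
  } else {
    integer(0)
  }
  for (i in planted) {
    k <- min(nrow(gpcr_assays), sample(8:20, 1))
    rows <- gpcr_assays[sample(nrow(gpcr_assays), k), ]
    evidence[[length(evidence) + 1]] <- tibble::tibble(
      compound_id = compounds$compound_id[i],
      assay_id = rows$assay_id
    )
    as_comment <- stats::runif(k) < 0.5
    score <- stats::runif(k, 1.5, 3.5)
    unit <- draw_units(k)
    value <- vapply(seq_len(k), function(j) {
      .score_to_value(score[j], unit[j], mw[i])
    }, numeric(1))
    censor <- !as_comment & stats::runif(k) < cfg$censored_fraction
    rec[[length(rec) + 1]] <- tibble::tibble(
      compound_id = compounds$compound_id[i],
      assay_id = rows$assay_id,
      target_id = rows$target_id,
      standard_type = ifelse(as_comment, "Inhibition",
                             sample(conc_types, k, replace = TRUE)),
      standard_relation = ifelse(censor, ">", "="),
      standard_value = ifelse(as_comment, NA_real_, value),
      standard_units = ifelse(as_comment, NA_character_, unit),
      activity_comment = ifelse(as_comment, "Not Active", NA_character_)
    )
  }

  # cardiovascular assays: potent for a subset of actives, weak otherwise
  cv_potent <- sample(active_idx,
                      round(cfg$fraction_active_also_cv_potent * n_active))
  is_cv_potent <- seq_len(n) %in% cv_potent
  cv_weak <- sample(setdiff(seq_len(n), cv_potent),
                    round(0.15 * n))
  if (nrow(cv_assays) > 0) {
    for (i in c(cv_potent, cv_weak)) {
      potent <- is_cv_potent[i]
      k <- min(nrow(cv_assays), 1 + stats::rpois(1, 1))
      rows <- cv_assays[sample(nrow(cv_assays), k), ]
      score <- if (potent) {
        pmax(stats::rnorm(k, 6, 0.4), 5.05)
      } else {
        pmin(stats::rnorm(k, 3, 0.7), 4.4)
      }
      unit <- draw_units(k)
      value <- vapply(seq_len(k), function(j) {
        .score_to_value(score[j], unit[j], mw[i])
      }, numeric(1))
      rec[[length(rec) + 1]] <- tibble::tibble(
        compound_id = compounds$compound_id[i],
        assay_id = rows$assay_id,
        target_id = rows$target_id,
        standard_type = sample(conc_types, k, replace = TRUE),
        standard_relation = "=",
        standard_value = value,
        standard_units = unit,
        activity_comment = NA_character_
      )
    }
  }

  if (cfg$n_orphans > 0) {
    rec[[length(rec) + 1]] <- tibble::tibble(
      compound_id = sprintf("ORPHAN%03d", seq_len(cfg$n_orphans)),
      assay_id = assays$assay_id[1],
      target_id = NA_character_,
      standard_type = "IC50",
      standard_relation = "=",
      standard_value = 1000,
      standard_units = "nM",
      activity_comment = NA_character_
    )
  }

  activities <- dplyr::bind_rows(rec)
  activities <- tibble::add_column(
    activities,
    record_id = sprintf("SYNREC%07d", seq_len(nrow(activities))),
    .before = 1
  )

  ev_counts <- if (length(evidence) > 0) {
    dplyr::count(dplyr::distinct(dplyr::bind_rows(evidence)),
                 .data$compound_id, name = "n_ev")
  } else {
    tibble::tibble(compound_id = character(), n_ev = integer())
  }
  gpcr_evidence_n <- ev_counts$n_ev[match(compounds$compound_id,
                                          ev_counts$compound_id)]
  gpcr_evidence_n[is.na(gpcr_evidence_n)] <- 0L

  truth_compounds <- tibble::tibble(
    compound_id = compounds$compound_id,
    true_active = true_active,
    latent_mtr1a = latent[, "MTR1A"],
    latent_mtr1b = latent[, "MTR1B"],
    latent_mtr1c = latent[, "MTR1C"],
    latent_mean = rowMeans(latent),
    is_cv_potent = is_cv_potent,
    n_gpcr_assays_planted = gpcr_evidence_n,
    gpcr_eligible = gpcr_evidence_n >= 10,
    mw = mw
  )
  list(
    activities = activities,
    compounds = compounds,
    assays = assays[, .assay_cols],
    truth = list(
      compounds = truth_compounds,
      assays = assays[, c("assay_id", "category")]
    )
  )
}

.make_assays <- function(cfg) {
  mel_templates <- c(
    "Binding affinity at human melatonin receptor %s (radioligand displacement)",
    "Displacement of [125I]iodomelatonin from %s expressed in CHO cells",
    "Agonist activity at %s receptor in functional GTPgammaS assay",
    "Inhibition of forskolin-stimulated cAMP via %s"
  )
  mel <- do.call(rbind, lapply(seq_along(.subtypes), function(s) {
    k <- cfg$n_melatonin_assays_per_subtype
    if (k == 0) return(NULL)
    data.frame(
      assay_id = sprintf("AMEL_%s_%02d", .subtypes[s], seq_len(k)),
      description = sprintf(sample(mel_templates, k, replace = TRUE),
                            .subtypes[s]),
      assay_type = sample(c("B", "F"), k, replace = TRUE, prob = c(.6, .4)),
      target_class = "GPCR",
      target_id = .subtypes[s],
      organism = sample(c("Homo sapiens", "Rattus norvegicus"), k,
                        replace = TRUE, prob = c(.7, .3)),
      cell_line = sample(c("CHO", "HEK293", ""), k, replace = TRUE),
      tissue = "",
      bao_format = sample(c("BAO_0000219", "BAO_0000221"), k,
                          replace = TRUE),
      category = "melatonin_subtype",
      stringsAsFactors = FALSE
    )
  }))

  gpcr_targets <- c("serotonin 5-HT2C", "dopamine D2", "histamine H1",
                    "adrenergic alpha-1A", "muscarinic M3", "opioid mu",
                    "adenosine A2A", "cannabinoid CB1")
  k <- cfg$n_gpcr_panel_assays
  gpcr <- if (k > 0) data.frame(
    assay_id = sprintf("AGPCR_%03d", seq_len(k)),
    description = sprintf("Binding affinity at %s receptor",
                          sample(gpcr_targets, k, replace = TRUE)),
    assay_type = "B",
    target_class = "GPCR",
    target_id = sprintf("GPCRT%03d", seq_len(k)),
    organism = "Homo sapiens",
    cell_line = sample(c("CHO", "HEK293"), k, replace = TRUE),
    tissue = "",
    bao_format = "BAO_0000219",
    category = "gpcr_panel",
    stringsAsFactors = FALSE
  ) else NULL

  cv_templates <- c(
    in_vivo = "Antihypertensive activity in vivo in spontaneously hypertensive rats (blood pressure)",
    in_vivo2 = "Effect on heart rate in vivo in anesthetized dogs",
    in_vivo3 = "Antiarrhythmic activity in vivo against ouabain-induced arrhythmia",
    in_vitro = "Inhibition of rat aortic ring contraction",
    in_vitro2 = "Negative inotropic effect in isolated guinea pig atria",
    in_vitro3 = "Vasodilator activity in isolated coronary artery",
    in_vitro4 = "Binding to cardiac L-type calcium channel in ventricular membranes"
  )
  k <- cfg$n_cv_assays
  cv <- if (k > 0) {
    tmpl <- sample(names(cv_templates), k, replace = TRUE)
    data.frame(
      assay_id = sprintf("ACV_%03d", seq_len(k)),
      description = unname(cv_templates[tmpl]),
      assay_type = "F",
      target_class = sample(c("Ion channel", "Tissue preparation",
                              "Enzyme"), k, replace = TRUE),
      target_id = sprintf("CVT%03d", seq_len(k)),
      organism = sample(c("Rattus norvegicus", "Cavia porcellus",
                          "Canis familiaris"), k, replace = TRUE),
      cell_line = "",
      tissue = sample(c("heart", "aorta", ""), k, replace = TRUE),
      bao_format = "BAO_0000218",
      category = "cv",
      stringsAsFactors = FALSE
    )
  } else NULL

  out <- tibble::as_tibble(dplyr::bind_rows(mel, gpcr, cv))
  out$cell_line[out$cell_line == ""] <- NA_character_
  out$tissue[out$tissue == ""] <- NA_character_
  out
}

#' Recovery metrics against the planted ground truth
#'
#' Compares pipeline outputs to the generator's ground truth: sensitivity
#' and specificity of hit calling against the true activity labels, AUROC
#' of the melatonin score for true activity, Spearman correlation between
#' melatonin score and latent potency, and the fraction of planted
#' cardiovascular-potent actives recovered in the CV hit table.
#'
#' @param truth Ground truth (`generate_synthetic_chembl()$truth`).
#' @param results Screen results ([screen()]).
#' @param cv_hits Optional CV hit list ([select_cv_hits()]).
#' @return A list of metrics.
#' @export
truth_report <- function(truth, results, cv_hits = NULL) {
  tc <- truth$compounds
  unknown <- setdiff(results$compound_id, tc$compound_id)
  if (length(unknown) > 0) {
    stop("screen results contain compound ids absent from the ground ",
         "truth: ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  idx <- match(results$compound_id, tc$compound_id)
  truth_lab <- tc$true_active[idx]
  hit <- results$is_hit

  sens <- if (any(truth_lab)) sum(hit & truth_lab) / sum(truth_lab) else NA
  spec <- if (any(!truth_lab)) sum(!hit & !truth_lab) / sum(!truth_lab) else NA
  auroc <- if (length(unique(truth_lab)) == 2) {
    as.numeric(pROC::auc(pROC::roc(
      response = truth_lab, predictor = results$melatonin_score,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    )))
  } else {
    NA_real_
  }
  rank_cor <- stats::cor(results$melatonin_score, tc$latent_mean[idx],
                         method = "spearman")

  cv_recovery <- NA_real_
  if (!is.null(cv_hits)) {
    planted <- tc$compound_id[tc$is_cv_potent]
    screened_planted <- intersect(planted, results$compound_id)
    if (length(screened_planted) > 0) {
      cv_recovery <- mean(screened_planted %in% cv_hits$hits$compound_id)
    }
  }
  list(
    n_compounds = nrow(results),
    sensitivity = sens,
    specificity = spec,
    auroc = auroc,
    score_latent_spearman = rank_cor,
    cv_recovery = cv_recovery
  )
}
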