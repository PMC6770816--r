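# Chemical descriptors and the weighted quantitative estimate of
# drug-likeness (QED), computed on top of OpenBabel (ChemmineOB).
#
# Molecular weights are formula-based (conventional atomic weights) so that
# masses agree with the values a chemist computes from the molecular formula.
# Polar surface area uses the Ertl fragment scheme restricted to N/O
# contributions (sulfur/phosphorus contributions subtracted from OpenBabel's
# extended total), matching the convention under which the QED desirability
# curves were fitted. logP is OpenBabel's Wildman-Crippen implementation;
# small deviations from other toolkits' atom typing are expected and are
# discussed in the methods vignette.

.parse_mols <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

.smarts_count <- function(mols, pattern) {
  as.numeric(ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE))
}

# element counts from a Hill-order molecular formula string, e.g. "C13H16N2O2"
.parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula, perl = TRUE)
  tokens <- regmatches(formula, m)[[1]]
  tokens <- tokens[tokens != ""]
  elements <- sub("^([A-Z][a-z]?).*$", "\\1", tokens)
  counts <- as.integer(sub("^[A-Z][a-z]?", "", tokens))
  counts[is.na(counts)] <- 1L
  # charge markers and isotopic labels are not elements
  ok <- elements %in% names(.atomic_weights) | elements %in% c("D", "T")
  stats::setNames(counts[ok], elements[ok])
}

.formula_weight <- function(formula) {
  counts <- .parse_formula(formula)
  w <- .atomic_weights[names(counts)]
  if (anyNA(w)) {
    stop("element(s) without tabulated atomic weight in formula ", formula)
  }
  sum(w * counts)
}

# asymmetric double sigmoid desirability, scaled to its maximum
.qed_ads <- function(x, p) {
  a <- p[1]; b <- p[2]; c0 <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  val <- a + b / (1 + exp(-(x - c0 + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - c0 - d / 2) / f)))
  val / dmax
}

.count_alerts <- function(mols, n_fluorine) {
  triggered <- rep(0L, length(n_fluorine))
  for (pat in .qed_alert_smarts) {
    triggered <- triggered + as.integer(.smarts_count(mols, pat) > 0)
  }
  # dot-disconnected families expressed as count rules
  triggered <- triggered +
    as.integer(.smarts_count(mols, .qed_ester_smarts) >= 3) +
    as.integer(n_fluorine >= 4)
  triggered
}

#' Compute chemical descriptors for SMILES structures
#'
#' Computes, per structure: formula-based molecular weight, Wildman-Crippen
#' logP, molar refractivity, N/O polar surface area, hydrogen-bond donor and
#' acceptor counts, strict rotatable bonds, aromatic ring count, heavy-atom
#' and element counts, the count of unwanted-substructure alert families
#' triggered, and the weighted quantitative estimate of drug-likeness
#' (`qed_weighted`).
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers used in error messages (defaults to the
#'   SMILES themselves).
#' @return A tibble with one row per input structure, in input order.
#'   Duplicate structures are computed once.
#' @export
compute_descriptors <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  if (is.null(ids)) ids <- smiles
  uniq <- unique(smiles)

  mols <- .parse_mols(uniq)
  props <- ChemmineOB::prop_OB(mols)
  if (nrow(props) != length(uniq)) {
    stop("OpenBabel returned ", nrow(props), " molecules for ",
         length(uniq), " SMILES inputs; check structure syntax")
  }
  n_heavy_chk <- .smarts_count(mols, "[!#1]")
  if (any(n_heavy_chk == 0)) {
    bad <- ids[match(uniq[n_heavy_chk == 0], smiles)]
    stop("unparseable SMILES for: ", paste(bad, collapse = ", "))
  }

  counts <- lapply(props$formula, .parse_formula)
  elem <- function(sym) {
    vapply(counts, function(x) {
      v <- x[sym]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  }
  mw <- vapply(props$formula, .formula_weight, numeric(1), USE.NAMES = FALSE)

  hba <- Reduce(`+`, lapply(.qed_acceptor_smarts,
                            function(p) .smarts_count(mols, p)))
  hbd <- .smarts_count(mols, .qed_donor_smarts)
  rotb <- .smarts_count(mols, .qed_rotb_smarts)
  arom <- Reduce(`+`, lapply(.arom_ring_smarts,
                             function(p) .smarts_count(mols, p)))
  sp_corr <- Reduce(`+`, lapply(names(.psa_sp_contrib), function(p) {
    .smarts_count(mols, p) * .psa_sp_contrib[[p]]
  }))
  psa <- pmax(props$TPSA - sp_corr, 0)

  n_c <- elem("C"); n_n <- elem("N"); n_o <- elem("O"); n_s <- elem("S")
  n_f <- elem("F")
  n_halogen <- n_f + elem("Cl") + elem("Br") + elem("I")
  n_h <- elem("H")
  heavy <- vapply(counts, function(x) {
    sum(x[setdiff(names(x), "H")])
  }, numeric(1))
  alerts <- .count_alerts(mols, n_f)

  qed_in <- cbind(MW = mw, ALOGP = props$logP, HBA = hba, HBD = hbd,
                  PSA = psa, ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(names(.qed_weights), function(k) {
    pmax(.qed_ads(qed_in[, k], .qed_ads_params[[k]]), 1e-12)
  }, numeric(length(uniq)))
  d <- matrix(d, nrow = length(uniq),
              dimnames = list(NULL, names(.qed_weights)))
  qed <- exp(as.vector(log(d) %*% .qed_weights) / sum(.qed_weights))

  out <- tibble::tibble(
    smiles = uniq,
    molecular_weight = mw,
    qed_weighted = qed,
    alogp = props$logP,
    molar_refractivity = props$MR,
    tpsa = psa,
    hbd = hbd,
    hba = hba,
    rotatable_bonds = rotb,
    aromatic_rings = arom,
    heavy_atoms = heavy,
    n_carbon = n_c,
    n_nitrogen = n_n,
    n_oxygen = n_o,
    n_sulfur = n_s,
    n_fluorine = n_f,
    n_halogen = n_halogen,
    n_hetero = heavy - n_c,
    n_alerts = alerts,
    mw_per_heavy_atom = mw / heavy,
    hetero_fraction = (heavy - n_c) / heavy
  )
  out[match(smiles, uniq), , drop = FALSE]
}

#' Weighted QED for one or more structures
#'
#' Convenience wrapper around [compute_descriptors()] returning only the
#' weighted quantitative estimate of drug-likeness.
#'
#' @inheritParams compute_descriptors
#' @return Numeric vector of QED values in `[0, 1]`.
#' @export
qed_weighted <- function(smiles, ids = NULL) {
  compute_descriptors(smiles, ids)$qed_weighted
}

#' Reference structures used in worked examples
#'
#' SMILES for melatonin (N-acetyl-5-methoxytryptamine, C13H16N2O2) and
#' tasimelteon, whose formula masses match their registered values.
#'
#' @return Named character vector of SMILES.
#' @export
reference_structures <- function() {
  c(
    melatonin   = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
    tasimelteon = "CCC(=O)NC[C@@H]1C[C@H]1c1cccc2c1CCO2"
  )
}

#' Bundled drug-like structure library
#'
#' A synthetic library of ~170 well-known drug-like structures bundled with
#' the package and used by the data generator so that chemical descriptors
#' are computable and realistic. Names are informal labels for simulation
#' purposes, not authoritative structure records.
#'
#' @return Tibble with columns `name` and `smiles`.
#' @export
drug_structure_library <- function() {
  path <- system.file("extdata", "druglike_smiles_synthetic.tsv",
                      package = "melscreen", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
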