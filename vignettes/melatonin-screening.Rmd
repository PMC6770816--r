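---
title: "Methods: melatonin potency scoring, random-forest screening, and cardiovascular cross-filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: melatonin potency scoring, random-forest screening, and cardiovascular cross-filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`melscreen` implements a triage pipeline for compounds with melatonin
receptor activity, from heterogeneous bioactivity tables to a ranked hit
list cross-filtered against cardiovascular assays. This vignette is the
package's account of the method: the model at each stage, the parameters
that matter, what the synthetic data generator does and does not emulate,
and the design choices that were genuinely open.

## The potency score

Bioactivity databases record the same kind of experiment in many
dimensions: IC50 in nM, Ki in µg/mL, EC50 in µM, percent inhibition at a
fixed dose. Potency comparisons require one scale. For every
concentration-typed record (IC50, EC50, Ki, Kd, AC50, Potency) the package
computes

$$\mathrm{score} = -\log_{10}\big(c \,/\, \mathrm{mol\,L^{-1}}\big),$$

so 1 µM maps to 6 and 1 nM to 9. Unit handling: nM and µM scale by
$10^{-9}$ and $10^{-6}$; µg/mL divides by the compound's molecular weight
(g/mol) after converting to g/L, and therefore requires a structure.
Non-concentration types (percent inhibition and the like) yield no score;
they are neither potency evidence nor silently coerced.

Censoring follows the record's relation. A `>` relation on a concentration
means the compound is *less* potent than the bound, so the derived score is
an upper bound (`censored = "at_most"`): it contributes no value to any
potency average but is retained as inactivity evidence. A `<` relation
gives a lower bound whose value is included as-is — it preserves the
direction of the information without inventing a magnitude. Mixed
measurement types (binding Ki vs functional IC50) are pooled without
offsets: the upstream curation this package mirrors pools functional and
binding experiments into one score, and no type-specific correction is
attempted. Scores are never clipped; the activity threshold lives
downstream.

## Subtype averaging

Melatonin activity is measured against three receptor subtypes (MT1/MTR1A,
MT2/MTR1B, and the MTR1C/GPR50-type third subtype). Their per-compound mean
scores are strongly correlated — the package reports Pearson and Spearman
coefficients per subtype pair, and on the default synthetic universe
(latent correlation 0.9) recovers r ≈ 0.92–0.94 over ~520–550 shared
compounds — which justifies collapsing them into a single **averaged
melatonin potency score**. The average is the *mean of subtype means*, not
the pooled-record mean, so a subtype assayed fifty times does not dominate
one assayed twice.

## The 60-variable validation set

Each activity record ("experimental fact") becomes one row with exactly 60
features spanning six families: 20 chemical descriptors, 14 assay
variables, 10 target variables, 6 taxonomy variables, 6 cell-line/tissue
variables, and 4 enumerated bookkeeping variables. The family structure
and the count are fixed; the identity of the variables inside each family
is this package's documented choice (the original 60 were never disclosed),
so the schema is constructed by `build_schema()` and fingerprinted, and
models refuse rows encoded under any other schema.

Chemical descriptors are computed from SMILES with OpenBabel (ChemmineOB):
formula-based molecular weight (conventional atomic weights, so melatonin's
C13H16N2O2 gives exactly 232.283 g/mol), Wildman–Crippen logP, molar
refractivity, N/O polar surface area, hydrogen-bond donors/acceptors,
strict rotatable bonds, aromatic rings, element counts, a
structural-alert count, and the weighted quantitative estimate of
drug-likeness (QED). The QED implementation is the package's own: the
eight published asymmetric-double-sigmoid desirability functions and
weights over MW, ALOGP, HBA, HBD, PSA, ROTB, AROM and ALERTS, with the
acceptor/donor/rotatable-bond SMARTS vocabularies and the 116-family
unwanted-substructure set evaluated through OpenBabel's SMARTS engine. Two
alert families are dot-disconnected patterns OpenBabel cannot parse (three
or more ester groups; four or more fluorines) and are implemented as
equivalent count rules. Polar surface area subtracts OpenBabel's sulfur
and phosphorus contributions to recover the nitrogen/oxygen-only
convention under which the QED desirabilities were fitted. One caveat is
deliberate: logP comes from OpenBabel's Wildman–Crippen atom typing, which
differs slightly from other toolkits (worst on sulfonamides); QED values
consequently differ from other implementations by ≤ 0.01 for typical
drug-like molecules, up to ~0.1 for a few sulfur-rich structures.

Categorical variables (assay type, organism, units, target class, ...) are
integer-encoded by a stable hash of the value, so codes never depend on
which rows happen to be in a batch and separately encoded sets remain
consistent. Missing numeric chemistry is imputed with the column median;
missing categoricals get the sentinel −1. Both choices suit random
forests, which split on arbitrary codes and tolerate sentinels.

The activity label is `active` iff the compound's averaged potency score
strictly exceeds 4.0. The original work states the *screening* call
("score > 4") but not the training label threshold; using the same
constant keeps the pipeline self-consistent end to end.

## The artificial inactive population

Melatonin-focused data contain almost no negative records, and
classification needs both classes. Negatives are harvested as compounds
with inactivity evidence in **at least 10 distinct GPCR-class assays**,
where evidence is any of: an activity comment containing "Not Active", a
measured potency score below 4, or an above-censored (`>`) record whose
bound is below 4. Distinct assays are counted, never records — twelve weak
records in six assays do not qualify. One inactive-labelled row per
sampled eligible compound is appended, encoded from one of the compound's
own evidence records, with placeholder activity score 0 (far below every
active threshold, keeping the regression target defined). Sampling is a
pure function of the eligible set, the target count, and the seed; the
published design's class ratio (60,000 negatives per 1,617 melatonin
molecules) is preserved at reduced scale by
`default_augment_count()`, capped at the eligible pool. Negatives are
sampled once per pipeline invocation under the recorded seed.

## Models, countRatio, and the combined melatonin score

The validation set is split 80/20 at the record level, reproducibly under
a seed. Two random forests are trained on the identical schema: a
classifier for the label and a regressor for the activity score, each 100
trees, unlimited depth, √p (classification) or p/3 (regression) candidate
features per split, single-threaded for reproducibility. No
hyperparameter search, cross-validation, calibration, or imbalance
weighting is performed: the negative population is the imbalance control
by construction.

Held-out evaluation removes the truth columns, predicts, and reports the
per-record and per-compound regression correlations, the confusion
matrix, and the distribution of **countRatio** — the fraction of a
compound's scored records the classifier calls active — stratified by true
label. Whether the original correlation figure was computed per record or
per compound is ambiguous, so both are emitted.

Screening applies the bundle to every record in the universe (streamed in
batches) and aggregates per compound. The final melatonin score is the
**measured** averaged potency score whenever one exists; only compounds
without measured evidence receive the model-derived score. The
combination of countRatio with the regression prediction is not specified
in the source work; this package uses their product,
`count_ratio × mean_predicted_score`, which damps compounds inconsistently
classified active while preserving magnitude, and isolates the rule in
`combine_score()` so a different rule is a one-line substitution.
Compounds with melatonin score strictly greater than 4 are hits; hits with
a non-empty preferred name form the named-drug table.

## Cardiovascular cross-filter

Cardiovascular assays are flagged by a configurable, audited keyword rule
over descriptions and tissue annotations (heart, cardiac, aort-, coronary,
arrhythmi-, blood pressure, hypertens-, vasoconstrict-, vasodilat-, atri-,
ventric-, vascular; stems are word-anchored so "pediatric" does not
match). How the original cardiovascular assays were designated is
undisclosed, so counts from this rule are not expected to match the
original ones. A **CV hit** is one record with in-assay potency score
strictly above 4.5, in a flagged assay, for a compound with melatonin
score strictly above 4; summaries count distinct records, assays, and
molecules, and the table splits into in-vivo and in-vitro halves
recognized from whole-animal wording. The compound–assay bipartite graph
labels molecules by drug name when one exists and marks the rest
anonymous, mirroring the convention of hiding bare registry numbers;
export is GraphML plus an edge-list TSV.

## The synthetic universe

The generator emulates the statistical structure the pipeline consumes,
with known ground truth. Defaults are the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_compounds` | 2000 | compound universe size |
| `fraction_melatonin_active` | 0.30 | true actives (exact count) |
| latent means | 7 / 2 | active / inactive mean log-potency |
| latent sd | 1.0 | spread of both populations |
| `subtype_correlation` | 0.9 | latent correlation across MTR1A/B/C |
| `noise_sd` | 0.5 | measurement noise, log units |
| `n_melatonin_assays_per_subtype` | 10 | 30 receptor assays total |
| `n_gpcr_panel_assays` | 50 | inactivity-evidence panel |
| `n_cv_assays` | 40 | cardiovascular assays |
| `fraction_active_also_cv_potent` | 0.25 | actives planted potent (score > 5) in CV assays |
| `unit_mixture` | 0.6/0.3/0.1 | nM / µM / µg·mL⁻¹ |
| `censored_fraction` | 0.1 | weak records reported as `>` |
| `percent_fraction` | 0.05 | percent-inhibition records |

Actives draw latent subtype potencies from an equicorrelated trivariate
normal (mean 7), inactives from mean 2; the threshold 4 separates the
populations with overlap controlled by `noise_sd`. Every measurement is
latent plus noise, re-expressed in a unit drawn from the mixture, so the
noiseless limit round-trips exactly through the potency transform — the
unit-invariance test bed. Structures are recycled from a bundled library
of ~170 well-known drug-like SMILES (labelled synthetic; names are
simulation labels, not authoritative structure records) so descriptors are
computable and realistic. The generator ledgers exactly which distinct
GPCR-class assays received inactivity evidence per compound — melatonin
receptor assays are GPCR-class and count too — so negative-population
eligibility has exact ground truth. At default scale the universe is
~23,000 records and the full pipeline runs in roughly half a minute on one
CPU; tests use smaller universes (120–700 compounds) chosen to keep the
whole suite within a few minutes.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: chemistry is uninformative by construction
(structures are recycled independently of activity), so the models' signal
lives in assay/target metadata, which is the easy half of the real
problem; real ChEMBL has document/citation structure, assay-quality
flags, heterogeneous curation errors, and activity cliffs none of which
are simulated; and real negatives are not missing at random. Recovery
metrics (AUROC ≥ 0.8, ≥ 80% of planted CV-potent actives) validate the
plumbing and the statistics, not chemical generalization.

## Numerical choices and degenerate inputs

* Unit conversion is exact arithmetic on doubles; unit invariance holds to
  1e−9 across nM/µM/M/µg·mL⁻¹ re-expressions.
* Correlations over fewer than 3 shared compounds are reported absent with
  their n; constant prediction vectors likewise yield an absent
  correlation rather than an error.
* Records with zero or negative concentrations, µg/mL records without a
  molecular weight, and unparseable numeric fields are counted, warned
  about, and excluded from scoring — never silently dropped from the
  table.
* The 80/20 split rounds to the nearest record and clamps so both halves
  are non-empty (5 rows give 4/1).
* All randomness (generation, negative sampling, splitting, forests) is
  seed-controlled; two runs with identical config and seed produce
  byte-identical output tables.

## Known limitations

The keyword CV flag is a transparent stand-in for undisclosed manual
curation; the 60-variable schema honors the stated families and count but
not the (unknown) original variables; the product combination rule is one
defensible reading of "a combination of countRatio and melatonin
prediction score"; logP (and hence QED's third decimal) is
toolkit-dependent; and absolute hit counts from the original ChEMBL-wide
campaign (9 k hits, 254 named drugs, 284/162/80 cardiovascular
records/assays/molecules) are release- and curation-dependent scale
references, not reproduction targets.
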