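---
title: "Methods: the fuzzy-rule / SVM cascade for biopsy-outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fuzzy-rule / SVM cascade for biopsy-outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzybiopsy)
```

## Scope and model

`fuzzybiopsy` predicts the binary outcome of an MRI-targeted (fusion)
prostate biopsy from six prebiopsy variables: PSA density (ng/mL², PSA
divided by MRI-measured prostate volume), digital rectal examination
(negative/positive), previous-biopsy status (no/yes), number of suspicious
mpMRI lesions, lesion location (peripheral vs transitional/anterior), and
PI-RADS score (3–5). The classifier is a cascade:

1. **Fuzzy inference system (FIS).** A Mamdani system — minimum for rule
   AND, maximum aggregation per consequent class, centroid defuzzification
   of the two clipped output membership functions to a crisp score in
   [0, 1]. The output terms are triangles peaking at 0 (negative) and 1
   (positive) that cross at 0.5, so the default decision threshold 0.5 is
   the point of equal support. A patient whose every rule activation is 0 is
   *not classified* (NC).
2. **Linear SVM.** NC patients are classified by a support vector machine
   with the linear kernel Φ(x, y) = xᵀy, trained on the *entire* training
   cohort (not only eventual NC patients) over the same six variables,
   one-hot encoded for categoricals and min–max scaled for numerics. Ties at
   margin exactly 0 are called positive: the clinical priority is a low
   false-negative count, so ambiguity resolves toward biopsy.

The cascade therefore always returns a label, and every fuzzy-stage decision
carries the list of fired IF–THEN rules with their activations — the
explainability contract of the model (`explain()`, `rulebase.json`).

The Mamdani choice (fuzzifier → rule base → inference engine → defuzzifier,
with min/max operators and centroid) is the classic architecture for this
component list; no Sugeno-type inference or membership-function tuning is
implemented.

## Automatic rule induction

The rule base is induced per outcome class in four steps:

1. **SOM clustering.** A 4×4 self-organizing map clusters the class's
   patients into up to 16 subgroups. Update rule: w ← w + φ·η·(x − w), with
   learning rate η = 0.4 and a three-level neighborhood φ: 1 at the winning
   neuron, 0.5 at lattice distance 1, 0 beyond. Lattice distance is
   Chebyshev by default (distance 1 includes diagonals, so a winner drags up
   to 8 neighbours), switchable to Manhattan. Weights initialise uniformly
   on [0, 1] from the seed; the presentation order is one seeded shuffle
   reused every epoch (50 epochs by default), so induction is fully
   deterministic given the seed. Winner ties resolve to the lowest neuron
   index.
2. **Binarization.** Each variable maps to exactly one binary item per
   patient. Numeric intervals are the regions where each fuzzy term is
   maximal (breakpoints at the membership-function crossings: 0.10 and 0.15
   ng/mL² for PSA density; 1.5 and 2.5 lesions), so a mined itemset
   translates literally into a fuzzy antecedent. Boundary values belong to
   the upper interval, consistent with the "equal or greater is positive"
   convention used throughout.
3. **FP-growth.** Frequent itemsets are mined per cluster with a
   within-cluster minimum support of 0.25 (default). The implementation
   builds a genuine FP-tree and mines conditional pattern bases recursively;
   the test suite checks it against exhaustive enumeration. Support alone is
   used — no confidence criterion — since each itemset is only a *candidate*
   antecedent, re-scored in the next step.
4. **Predominance filtering.** Every candidate antecedent is recounted on
   the full training cohort, both classes. The predominance ratio is
   `max(n_pos, n_neg) / max(1, min(n_pos, n_neg))`; a rule is kept when the
   ratio reaches the threshold and at least one patient matches, with the
   majority class as consequent (so clusters of either class can contribute
   rules for either consequent — the counts decide). Duplicate antecedents
   from different clusters are merged; provenance records every source
   cluster.

### Why the predominance default is 3.0

The filter's purpose is to keep rules that are *strongly* one-class. A 2:1
ratio is weak evidence at realistic prevalences: with ~57% positive biopsies
the cohort's own odds are already 1.3:1, so 2:1 rules are close to
uninformative, they flood the rule base with broad single-item antecedents,
and the fuzzy stage then covers essentially every patient while frequent
exact activation ties (crisp terms give activations of exactly 1 on both
sides) defuzzify to 0.5. In that regime the fuzzy stage both stops being
selective and overrides the SVM stage entirely. At 3:1 the minority class is
capped at 25% of a rule's matches, rule bases stay in the tens-to-hundreds,
and a meaningful share of patients still reaches the SVM stage — the regime
the cascade is designed for. The threshold, like the minimum support, is a
plain argument (`predominance_threshold`) and can be set to any value.

## Membership functions

The study population's membership-function parameters are not published, so
the shipped defaults are explicit modelling assumptions, all replaceable via
`fis_config()`:

| variable | terms | breakpoints | rationale |
|---|---|---|---|
| psa_density | low / medium / high | crossings at 0.10, 0.15 ng/mL² | widely used clinical cut-offs for biopsy decisions |
| n_lesions | one / two / three_plus | crossings at 1.5, 2.5 | integer counts; terms peak on 1, 2, ≥3 |
| pirads | 3 / 4 / 5 | crisp singletons | ordinal score with no meaningful in-between |
| dre, prior_biopsy, lesion_location | category levels | crisp 0/1 | binary findings |

Numeric terms overlap linearly so every in-range value has positive total
membership; categorical terms are crisp indicators.

## Synthetic-cohort generator

The development cohort is not deposited, so `generate_synthetic_cohort()`
emulates it: n = 1448 with 56.9% positive biopsies (validation: 181 at
65.2%), normal age (mean 69, SD 8 years), log-normal PSA density (mean 0.17,
SD 0.17 ng/mL²), prostate volume (55.8, SD 27.8 cc) and lesion volume (0.98,
SD 1.91 cc) — log-normal because these quantities are right-skewed with SD
of the order of the mean, where a normal would generate negative values —
12% positive DRE, 85.5% peripheral lesions, and PI-RADS 3/4/5 at
27.9/56.6/15.5%. PSA is computed as PSA density × prostate volume, so the
two are consistent by construction.

Class-conditional structure follows the pattern of significant differences
in the development population — age, PSA density, DRE rate, both volumes and
the PI-RADS distribution shift with the outcome; PSA itself, lesion count
and location do not. The published material gives no effect sizes, so the
defaults (for example a +0.07 ng/mL² PSA-density class-mean difference, DRE
positivity 5.4% vs 17%, PI-RADS 3/4/5 of 41/53/6% vs 18/59/23%) are
assumptions chosen once to preserve the marginals above at the default
prevalence; every one of them is a `cohort_spec()` parameter. For numeric
variables the class means are placed symmetrically around the marginal mean
(`delta` = positive-minus-negative difference), so the documented marginal
moments hold at any prevalence.

What the generator does **not** emulate: correlations between variables
beyond the PSA identity (e.g. PI-RADS vs lesion volume), the repeat-biopsy
substructure, missingness patterns, and inter-centre drift between training
and validation cohorts. Tests passing on synthetic cohorts therefore
validate the *machinery* — determinism, coverage, counting identities,
discrimination under known signal — not clinical performance on real
patients, which requires external data.

## Numerical choices and degenerate inputs

- **Defuzzification** integrates the aggregated output set on a 201-point
  uniform grid over [0, 1] with trapezoid weights; for the piecewise-linear
  sets involved the centroid error is O(10⁻⁵), well below the 0.5 decision
  granularity.
- **ROC curves** sweep every unique score, calling positive at score ≥
  threshold. AUC is the trapezoid rule, which equals the tie-corrected
  Mann–Whitney statistic (tested). The optimal threshold maximizes Youden's
  J; among J-ties the lowest threshold is taken (sensitivity-favouring),
  and the criterion can be switched to closest-to-(0,1).
- **Percentages** are rounded half-up to one decimal, matching the
  convention of the published tables; base R's `round()` is half-even and
  would disagree on exact .x5 cells.
- **Gower distance**: numeric contributions are range-normalized from the
  training cohort and frozen; PI-RADS and lesion count stay numeric to keep
  their ordering; zero-range variables are a parameter error in the distance
  (they carry no information) while the SVM/SOM encoder maps a constant
  variable to a constant coordinate instead of failing.
- **KNN ties**: all records tied with the k-th neighbour distance enter the
  vote; a tied vote returns negative. Both rules make the classifier
  invariant to training-row order.
- **Subset search** scores each of the 2^p − 1 candidate subsets by
  stratified 5-fold cross-validated accuracy (the scoring scheme of the
  selection procedure is not published; 5-fold stratified CV is the
  conventional default and is seed-controlled). Ties order toward smaller
  subsets, then lexicographically. Per-variable dissimilarity matrices are
  precomputed once, so any subset's Gower matrix is a mean of slices.
- **Cascade ROC scores**: the cascade itself returns labels, not
  probabilities. For threshold sweeps the package uses the defuzzified score
  where the FIS classified and the logistic-squashed SVM margin
  (1/(1+e^(−m))) elsewhere — monotone in each stage's own evidence and equal
  to 0.5 exactly at each stage's decision boundary.
- **Cohorts with one class**, empty rule bases, unparseable CSV fields,
  out-of-domain categories (e.g. PI-RADS 6), and records missing any of the
  six inputs are all hard errors or, for missingness, explicit
  ineligibility warnings — never silent drops or imputation.

## Problem sizes in the test suite

The suite exercises mining equivalence on 100 random transaction sets (≤30
transactions, ≤12 items), KNN against a brute-force oracle at n = 40,
end-to-end coverage and explainability at n = 2000, discrimination sanity at
n = 2000 (strong signal, and label-permutation chance checks) and logistic
coefficient recovery at n = 5000 — sizes chosen so each property is tested
at the scale where its failure modes appear while the whole suite stays
fast.

## Known limitations

- The induced rule count and fuzzy-stage coverage depend on the unpublished
  membership-function and mining parameters; with the shipped defaults the
  package produces larger rule bases than the development system's 29 rules,
  which is expected given the predominance/support settings are assumptions.
- The net-benefit column of the development study's result table uses a
  variant formula that cannot be reconstructed from the published counts;
  the package implements standard decision-curve net benefit
  (TP/n − FP/n · p_t/(1 − p_t)) and makes no attempt to reproduce those
  point values.
- No probability calibration: the cascade's score is an ordering device, not
  a calibrated risk (the fuzzy stage and SVM margins live on different
  evidence scales), so calibration plots are out of scope by design.
- Linear kernel only, no rule-weight learning, no imputation.
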