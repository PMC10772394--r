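---
title: "RPPA signaling analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RPPA signaling analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppasig)
```

# Scope

`rppasig` implements the analysis chain used for reverse-phase protein
array (RPPA) profiling of pre-treatment tumor biopsies in a neoadjuvant
breast-cancer trial setting: spot-level quantification, array batch
harmonization, per-analyte association screens against pathologic
complete response (pCR), unsupervised signaling-cluster definition,
distant recurrence-free survival (DRFS) analysis, and a two-phosphoprotein
response-predictive signature (HARPS). Each stage is an exported function
operating on plain tables and matrices; `run_pipeline()` chains them
through documented files so that any stage can equally be run on matrices
exported from a public repository.

# Quantification

An RPPA endpoint is one antibody target ("analyte") measured on triplicate
spots. For each (sample, analyte) the endpoint value is

1. per-replicate subtraction of the negative-control (secondary-antibody
   only) spot intensity from the primary-antibody spot intensity,
2. the mean of the three net intensities,
3. division by the sample's total-protein value (the mean of its three
   Sypro staining replicates).

Because the mean is linear, pairing primary and negative spots by
replicate index is numerically identical to subtracting the two replicate
means; the pairing convention is fixed for clarity only. Negative net
values are retained rather than floored at zero: the downstream
standardization is location–scale based, and flooring would bias
low-expressing samples upward. No log transform is applied at this stage;
harmonization consumes the ratio scale directly.

# Batch harmonization

Arrays are run in batches, and each (array, analyte) pair can carry both
an additive offset and a multiplicative gain. Harmonization standardizes
each array before combining:

* draw `B = 5000` subsamples of the array's patients, each maintaining a
  fixed receptor-subtype balance (HR+HER2− 0.384, TN 0.368,
  HR+HER2+ 0.158, HR−HER2+ 0.09);
* per analyte, record each subsample's mean and SD (n − 1 denominator);
* z-score the analyte with `mu` = mean of the subsample means and
  `sigma` = mean of the subsample SDs.

Since every (array, analyte) receives one affine transform, the procedure
removes any per-(array, analyte) affine batch effect exactly, up to
Monte-Carlo error in `(mu, sigma)`; the subtype balancing makes the
reference population comparable across arrays that accrued different
subtype mixes.

Design points that were genuinely open:

* **Subsample size.** The procedure fixes the subtype *balance*, not the
  subsample *size*. The default draws 80% of the array's patients without
  replacement (`subsample_fraction = 0.8`): without-replacement
  subsetting is the most direct reading of "sampling while maintaining a
  balance", and an 80% fraction keeps the per-subsample SD estimates
  stable. With the fraction at 1 and the proportions set to the array's
  empirical proportions, the whole procedure provably collapses to plain
  per-array column z-scoring, which the tests assert to 1e-9.
* **Per-array streams.** Subsamples are drawn independently per array
  (each array is standardized before combining); no joint draw across
  arrays is attempted.
* **Stratum rounding.** Stratum sizes are the largest-remainder rounding
  of `m * proportions`, capped at the stratum's population on the array;
  a required stratum with no members is an error naming the array and
  subtype.
* **Degenerate analytes.** A near-constant analyte is floored at
  `sd_floor = 1e-8` and flagged with a warning, never silently dropped.
* **Proportions.** The four subtype proportions are fixed constants of
  the configuration, used verbatim rather than re-estimated from data.

# Association screens

Each analyte is tested individually with a logistic model of pCR,
adjusted for the stratifying covariates of the scope: HR + HER2 + arm in
the whole population, HR + HER2 within an arm (each included only when
both levels are present — "as appropriate"), and arm within a receptor
subtype. The test is the likelihood-ratio test of the biomarker term,
`2(ll_full − ll_reduced)` against chi-squared(1). Benjamini–Hochberg
correction is applied within each screen's family (one family per scope),
with `significant` meaning BH p < 0.05 and `nominal` meaning raw
LR p < 0.05. Non-convergent or separated fits are flagged, carry missing
p values, and are excluded from the BH family rather than crashing the
screen. Analytes with less than 80% unmasked coverage within a scope are
not tested (`min_coverage`).

Between-group differential expression (e.g. one cluster against all
others within a subtype) uses the analogous Gaussian linear-model
likelihood-ratio test of the group term, again BH-corrected within the
screen; rank tests are deliberately not used so that the two screens
share one testing framework.

# Signaling clusters

Patients are clustered on the harmonized matrix with distance
`d = 1 − r` (Pearson correlation across shared analytes,
pairwise-complete over masked cells) and complete linkage. The distance
deliberately lives on the `[0, 2]` scale — the configured default cut
height of 1.54 only exists on that scale. Cluster labels are numbered by
dendrogram order, so they are stable under row permutations of the input.
A designated cluster (by default the largest, in `run_pipeline()`) can be
sub-split into its two top subtree branches; for complete linkage,
re-clustering a cluster's members reproduces its subtree exactly, so the
split is implemented as a k = 2 cut of the re-clustered submatrix and
labelled `<id>a` / `<id>b` by subtree position. Patients must share at
least `min_shared_analytes = 30` analytes with every other retained
patient; offenders are removed greedily (worst first) with a warning.

The number of clusters produced by a fixed-height cut is a property of
the data, not of the package: on the synthetic cohorts the default cut
yields far fewer clusters than a real trial cohort does, because the
generator's block-correlation structure is much simpler than real
signaling biology.

# Survival analysis

DRFS is analysed with the product-limit estimator and Cox proportional
hazards models (Efron tie handling, the default of the survival package
family). Per cluster, a Cox model with pCR as the exposure estimates the
hazard ratio with a Wald 95% CI; clusters with no events or single-class
pCR are flagged rather than fitted. Within each cluster's non-responders,
a per-analyte Cox screen adjusts for HR and HER2 (when they vary),
reports likelihood-ratio p values (consistent with the logistic screens;
Wald p values are also emitted), and applies BH within the cluster's
family. Clusters with fewer than 10 non-responders or fewer than 3 events
are skipped with a warning. Monotone-likelihood fits are flagged with
infinite confidence bounds and never enter a BH family.

# HARPS

The HER2 activation response predictive signature dichotomizes patients
by co-activation of phospho-EGFR Y1173 and phospho-ERBB2 Y1248. Each
marker's cut point is derived independently by Youden-index ROC analysis
(`J = sensitivity + specificity − 1`, positivity `value >= cut`,
candidate cuts at midpoints between consecutive distinct values plus the
infinite extremes, ties resolved toward the lowest cut) against pCR in
the derivation cohort — by default TN patients on the neratinib arm — on
the harmonized (z-scored) scale. HARPS+ requires *both* markers at or
above their cuts; the AND rule and the `>=` boundary convention are
stored in the serialized model so alternative combination rules can be
added without breaking compatibility. The derived cuts are then
extrapolated to the full TN population to tabulate response by arm and
HARPS status.

# The synthetic cohort generator

Every stage is verified against cohorts with known ground truth. The
generator emulates, at its defaults, the structure of the motivating
trial population: 736 patients across 8 arms (control, neratinib,
veliparib/carboplatin, AMG386, MK2206, trastuzumab/pertuzumab, TDM1/P,
PD1 inhibitor) with HER2-eligibility-respecting allocation weighted by
the observed per-arm sizes; subtype proportions 0.384/0.368/0.158/0.09;
139 analytes on 3 contiguous-accrual array batches with per-(array,
analyte) additive shifts (SD 0.5) and multiplicative gains (log-SD 0.2);
block-correlated latent signaling (round-robin pathway blocks of ~10
analytes, within-block correlation 0.5) with subtype-linked mean offsets
(HER2 block elevated in HER2+ subtypes, endocrine block in HR+ subtypes,
immune block in TN); five planted analytes with |beta| = 0.6 on the pCR
logit (positive for the two HER2-activation markers, negative for the
cyclin D1 / ER alpha / AR S650 resistance markers); per-subtype baseline
pCR rates of 18% (HR+HER2−), 40% (TN) and 62% (HR−HER2+) with 38% for
HR+HER2+ (a realistic value for a HER2-targeted-therapy-era HR+HER2+
cohort; the first three are the observed rates the generator emulates);
and exponential DRFS with baseline hazard 0.05/year, hazard ratio 0.25
for pCR, and administrative censoring at 10 years.

The latent-to-intensity map exponentiates the latent Gaussian
(`intensity = 10 * exp(0.25 z)`), giving the positive, right-skewed
intensities fluorescence produces; the modest log-scale (0.25) keeps the
map near-linear so that z-scoring the ratio-scale endpoint recovers the
latent values with per-analyte correlation above 0.95 at full size.
Replicate noise is mean-unbiased multiplicative log-normal with CV 0.05,
total-protein loading is log-normal (log-SD 0.2), and the
negative-control background is 0.5 on the endpoint scale. With replicate
noise at zero the quantification stage recovers the generator's batched
endpoints exactly, which the tests assert.

Per-analyte effect sizes are not published quantities; |beta| = 0.6 was
chosen once for testability (comfortably detectable at n = 736 after BH
correction) rather than realism. One global RNG stream is seeded from the
configuration; the spot-noise stage derives its own stream
deterministically, so cohorts and spot tables are bit-reproducible.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: adaptive randomization (allocation weights are
static), the real correlation topology of signaling networks (blocks are
disjoint and exchangeable, so fixed-height cuts produce fewer clusters
than real cohorts), informative censoring, missing-at-random DRFS
follow-up, non-proportional hazards, and assay artifacts beyond affine
batch effects (e.g. spatial gradients or saturation).

## Test-design notes

Two verification experiments deserve explicit rationale, decided when the
experiments were designed:

* **Type-I error of the screen.** The false-positive check runs on a
  cohort of mutually independent, effect-free analytes (block correlation
  zero), because the binomial reference band presumes independent nulls —
  and in the default generator the correlated block-mates of a planted
  analyte are *truly* associated with response through that correlation,
  so they are not null at all. Planted-effect recovery, by contrast, runs
  under the full default structure.
* **HARPS cut recovery.** The derivation-cohort fixture gives the two
  markers a shared-signal correlation of 0.85 — the co-activation premise
  of the signature itself — centered at 0.35 so the planted cut z = 0.7
  sits inside the data mass, with response probability stepping from 0.05
  to 0.95 at the cut. With independent markers the AND rule caps each
  marker's marginal response contrast so low that no cut-point method
  could localize the step at n = 150; with co-activated markers the
  Youden cut concentrates within a few inter-point gaps of the truth.

## Problem sizes used by the tests

The full-size study conditions (736 x 139, 3 arrays, B = 5000) are used
for the harmonization-recovery and screen-recovery checks; the null-size
check uses 208 analytes at n = 736 with B = 300 (harmonization precision
is immaterial to the size of the test); survival recovery uses n = 2000;
HARPS derivation n = 150; determinism and orchestration checks run at
n = 400 with 25 analytes and B = 60. Unit tests use cohorts of 120-400
patients. `scripts/acceptance.R` recomputes the same quantities from
scratch at the same sizes.

# Numerical conventions

* SDs use the n − 1 denominator throughout.
* BH adjustment excludes missing (flagged) p values from the family.
* Youden ties resolve toward the lowest cut; positivity is `>= cut`.
* Complete-linkage agglomeration inherits the reference implementation's
  deterministic tie handling; on continuous data ties have measure zero,
  and the tests compare trees against a naive O(n^3) agglomeration with
  lowest-index tie-breaking on tie-free instances.
* Analyte names are normalized at import (Unicode minus and en/em dashes
  to ASCII hyphen) because public exports mix dash glyphs; patient and
  analyte identifiers are otherwise case-sensitive exact keys.
* Matrices are written with 17 significant digits; every reader/writer
  round-trips to at least 1e-12 relative tolerance.

# Known limitations

* The harmonization contract assumes each array's subtype strata are
  populated; arrays missing a required subtype fail loudly rather than
  re-weighting.
* The per-analyte screens treat analytes as separate hypotheses; no
  attempt is made to model the correlation between analytes in the
  multiplicity correction (BH is used exactly as specified).
* The sub-split of a cluster is operationalized as the k = 2 subtree cut;
  where an original analysis justified a split by inspection, the subtree
  cut is a deterministic stand-in whose agreement with any particular
  manual split is not guaranteed.
* Alternative batch-correction methods (empirical-Bayes location/scale
  adjustment, quantile normalization) are intentionally out of scope:
  the balanced-resampling standardization is the procedure under study.
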