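---
title: "Comparing proliferation markers with commercial-style gene signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing proliferation markers with commercial-style gene signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolifsig)
```

## The scientific question

Lymph-node-negative breast cancer patients mostly do well, yet guideline-based
adjuvant treatment reaches far more patients than would relapse untreated.
Commercial gene-expression assays (the 21-gene recurrence score behind
Oncotype DX; the 70-gene prognosis profile behind MammaPrint) promise better
triage, but most of their prognostic information is carried by
proliferation-related genes. Direct tissue proliferation markers — the mitotic
activity index (MAI, mitoses per standardized tumour area), phosphohistone H3
(PPH3, an immunohistochemical mitosis count, conventionally dichotomized at
13) and Ki67 (percent positive tumour cells, dichotomized at 10%) — measure
the same biology at a fraction of the cost. This package implements, as
reusable and tested components, a pipeline that puts both kinds of markers on
the same footing: distant-metastasis-free survival (DMFS) in a node-negative
cohort, analysed per risk factor with Kaplan-Meier curves, log-rank tests and
Cox proportional-hazards models.

## Pipeline stages and their assumptions

**Endpoint encoding.** DMFS counts distant metastasis and breast-cancer death
as events. Other-cause death, locoregional recurrence, second primaries and
contralateral disease censor at the last follow-up visit; a confirmed
metastasis without a recurrence date is dated to the last follow-up visit.
`encode_dmfs()` accepts either a pre-encoded (time, event) pair or an
event-type column and applies these rules.

**Recurrence score.** `oncotype_group_scores()` combines the 16 target genes
into the published group scores (GRB7 group `0.9*GRB7 + 0.1*ERBB2`; ER group
`(0.8*ESR1 + 1.2*PGR + BCL2 + SCUBE2)/4`; proliferation group: mean of BIRC5,
MKI67, MYBL2, CCNB1, AURKA; invasion group `(CTSL2 + MMP11)/2`; CD68, GSTM1
and BAG1 as single-gene terms), and `oncotype_rs_unscaled()` applies the
published weights (+0.47, −0.34, +1.04, +0.10, +0.05, −0.08, −0.07). The
original algorithm operates on reference-normalized qPCR values with group
floors (8 for GRB7, 6.5 for proliferation) and a 0–100 rescale. On microarray
data we compute the score on per-gene z-scored expression, where the floors
are meaningless; because the risk groups are subsequently derived from
ROC-optimized cut-offs, only the *ordering* of the score matters, so floors
and rescale are optional and off by default (`floors = TRUE` restores the
clamping for qPCR-scale input).

**MammaPrint-style grouping — two routes.** The literature describes two ways
of turning the signature genes into a two-level risk group, and the pipeline
implements both without assuming they agree:

1. *AGPP correlation* (`agpp_centroids()`, `classify_agpp()`): average the
   expression profile of patients with and without metastasis over the
   signature genes, correlate each sample with both profiles, and call the
   sample good-prognosis iff its correlation with the no-metastasis profile
   is the larger (ties default to good — the explicit, lower-treatment
   choice). Pearson correlation is the default; Spearman (average ranks on
   ties) is available. Note that these centroids are fitted on the same
   cohort's outcomes, so group separation estimated by resubstitution is
   optimistic.
2. *Two-cluster analysis* (`two_cluster_risk()`): agglomerative clustering of
   samples on the signature genes with distance `1 − correlation` and average
   linkage (the convention of the dChip software family; the linkage is
   configurable), cut into two clusters; the cluster with the higher observed
   event proportion is labelled high-risk (equal proportions: the cluster
   with higher mean signature expression, a documented tie-break). This route
   is unsupervised up to the final labelling.

**ROC cut-offs and three risk groups.** `roc_curve()` evaluates sensitivity
and specificity at every midpoint between adjacent distinct scores (plus
±Inf sentinels, so the degenerate all-high and all-low operating points are
included) and integrates the AUC by trapezoid. "Optimal" cut-off means the
threshold whose operating point is closest, in Euclidean distance, to the
ideal corner (0, 1) of the ROC plane; ties break toward higher specificity,
then the lower threshold. Because "closest to 1" is ambiguous in common
usage, Youden's J is provided as an alternative criterion. The secondary
cut-off is the most specific threshold in the highly sensitive part of the
curve; "highly sensitive" is parameterized as sensitivity ≥ 0.9 (no published
number exists, so the bound is a documented default). Scores then map to
low / medium / high with intervals closed on the high-risk side
(`score >= cut_high` is high).

**Supervised gene selection.** `anova_per_gene()` computes a classical
equal-variance one-way two-group ANOVA per gene, vectorized over genes
(identical to per-gene `aov()` fits, which the test suite verifies). With two
groups, F equals the squared pooled t statistic, so the screen is
sign-agnostic and also captures genes expressed *lower* in metastasizing
tumours. Selection keeps genes with p ≤ 0.01 with **no** multiplicity
correction — deliberately liberal, exactly because the cross-validation stage
is designed to expose the optimism of such a selection.

**Leave-one-out cross-validation with reselection.**
`loocv_with_reselection()` repeats, for every held-out sample, the entire
supervised pipeline on the remaining samples: per-fold gene standardization
(training means and SDs, applied to the held-out sample), per-fold ANOVA
selection, and nearest-centroid classification by correlation to the
per-class mean profiles of the selected genes. Folds with an empty selection
predict the training-majority class so confusion counts always sum to n.
Standardizing *inside* the fold matters: z-scoring the full matrix first
forces each gene's row mean to zero, which makes the held-out value equal
minus the training sum and the two class centroids exactly anti-correlated —
a subtle leak that can push apparent accuracy far from its honest value. A
dedicated test asserts that scrambling the held-out sample's values leaves
that fold's gene list unchanged.

Two properties of the correlation classifier deserve emphasis. First, it
compares profile *shapes*: a class difference that shifts all selected genes
by the same amount is invisible after per-sample centring, so informative
signatures need heterogeneous effect directions or magnitudes. Second, on
weak signals at cohort scale (≈ 30 events in 94 patients), LOOCV accuracy is
highly variable between realizations because all folds share n − 2 samples;
individual realizations can even land below chance (an "anti-learning"
configuration). The acceptance script therefore reports LOOCV metrics
averaged over five replicate cohorts.

**Survival machinery.** Kaplan-Meier curves, log-rank tests and Cox models
are delegated to the survival package (`survfit`, `survdiff`, `coxph`) behind
small wrappers that fix the conventions: Breslow tie handling (Efron
available), Wald 95% CIs `exp(coef ± 1.96·SE)`, per-covariate Wald p-values,
and explicit errors for constant covariates, more covariates than events, and
monotone partial likelihoods. The test suite checks every wrapper against an
independent hand-coded oracle: a direct product-limit accumulation (1e-12),
a hypergeometric log-rank tabulation (1e-10) and a grid search of the Breslow
partial likelihood (1e-4). Stepwise selection (`cox_forward_wald()`) adds the
candidate with the smallest Wald p below `p_enter` (default 0.05, the common
software default) until none qualifies, or drops the largest p from the full
model in backward mode. The multivariate candidate set in the full pipeline
is the factors univariately significant at p < 0.05 on the log-rank test
(threshold configurable); the three-level MAI recoding is excluded there to
avoid entering MAI twice.

**Report.** `run_full_analysis()` emits a per-factor table — group label,
events/at-risk, event-free percent, log-rank p, HR with CI against the first
(reference) level — mirroring the layout such studies print.
`event_free_percent()` rounds half away from zero, the convention that
reproduces printed integers such as 63 from 6/16 (62.5%).

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions under which every claim in
the test suite is evaluated. Each patient carries a latent proliferation
score `z ~ N(0,1)`; a signature score `s = 0.6·z + 0.8·e` models the
well-documented fact that prognostic signatures are substantially
proliferation-driven. Expression on the log2 scale: every gene has a
patient-independent baseline `N(7, 1)`; a 50-gene proliferation module
(including the five recurrence-score proliferation genes) loads on `z` with
loading 1.0; the embedded signature genes (62 of the 70 shipped entries —
the eight contig-style identifiers stay unmatched, as on real annotated
platforms) load on `s`; all other genes, including the remaining
recurrence-score genes, are `N(0, 1)` noise around their baselines. The
noise SD of 1.0 with loading 1.0 encodes a per-gene signal-to-noise ratio
of one, a conventional magnitude for log2 microarray data.

Tissue markers are monotone noisy transforms of the same latent score:
`MAI = round(exp(log 8 + 0.9 z + 0.4 ε))`,
`PPH3 = round(exp(log 13 + 0.9 z + 0.35 ε))`,
`Ki67 = round(100 · logistic(−2 + z + 0.5 ε))`. The medians sit at the
conventional clinical cut-points, so the default 94-patient cohort splits
close to the emulated study's groups (e.g. PPH3 < 13 vs ≥ 13 near 45/49);
the smaller transform noise relative to single-gene expression noise encodes
the premise that counting mitoses measures proliferation more directly than
any individual transcript.

Survival follows a proportional-hazards model with linear predictor
`log(2.5)·z + log(1.3)·s` by default — hazard ratios per unit latent score
chosen to emulate a cohort in which the dichotomized proliferation marker
shows an HR near 3 while signature groupings show HRs in the 1.3–1.8 range.
Event times are exponential (a Weibull shape parameter generalizes this);
censoring is an independent uniform dropout time on (0, 171] months for 90%
of patients and administrative at 171 months (the follow-up range of the
emulated cohort) for the rest. The baseline hazard is not a free choice: it
is calibrated by numerical integration and root-finding so the expected
observed event fraction equals the 24% target, whatever the effect sizes.
Age, diameter, grade, ER/PR/HER2/CK5/6 statuses are drawn with marginals
near the emulated cohort's Table; receptor positivity is weakly negatively
coupled to `z`.

What the generator does **not** emulate: probe-level artifacts, batch
effects, normalization pipelines, missingness, platform-specific intensity
distributions, or any correlation structure beyond the two planted modules.
Passing tests therefore demonstrate that the pipeline's statistics behave
correctly under a clean proportional-hazards world with known truth — not
that any particular cohort's published numbers would be reproduced from its
raw data.

## Numerical choices and degenerate inputs

* Gene standardization uses the population SD (denominator n), so a
  z-scored row has exactly unit SD under that convention; zero-variance
  genes are an error (the pipeline drops them before standardizing).
* Probe collapse keeps the probe with the highest mean expression
  (`method = "mean"` averages instead); exact mean ties keep the first
  probe in row order.
* Correlation-undefined situations (constant sample, constant centroid,
  single-gene selection) raise errors, except in the one-gene
  nearest-centroid case, which falls back to absolute distance.
* `assign_three_groups(cut, cut)` yields an empty medium group; when the
  high-sensitivity cut-off exceeds the optimal cut-off (possible on
  degenerate ROC curves), the pipeline collapses the two cuts rather than
  reordering them.
* All simulation randomness flows from one integer seed;
  identical configurations are bit-identical.

## Problem sizes in the test and acceptance suites

Chosen to make the statistical claims sharp while keeping a full run in the
tens of seconds: null calibration of the log-rank test uses 500 replicates
of 60 patients; selection calibration uses 1,000 null genes in 40 samples
(binomial 99% band around 1%); hazard-ratio recovery uses 100 replicate
cohorts of 400 patients with a planted HR of 3 on the continuous latent
score (a dichotomized surrogate would *not* have HR 3 — the marginal HR of
a median split of a continuous log-linear effect is larger, about 3^1.6);
the factor-ordering experiment uses 50 cohorts of 94 patients with the
signature effect set to zero, comparing the PPH3 dichotomy against the
ROC-derived recurrence-score groups and the two-cluster signature grouping
(the AGPP route is excluded from that comparison precisely because its
resubstitution training on the outcome makes it an unfair comparator).

## Known limitations

* The recurrence-score risk groups depend on outcome-derived ROC cut-offs,
  so they are cohort-specific and optimistically separated; the published
  fixed clinical cut-offs cannot be applied to z-scored microarray values.
* The 70-entry signature ships under one common symbol mapping; annotation
  vintages differ, and `map_signature()`'s case-insensitive matching plus
  the returned `missing` list are the only concession to that.
* The per-gene screen ignores correlation between genes; the selected-set
  size at a fixed alpha is strongly driven by the planted module's internal
  correlation, which is why replicate cohorts select anywhere from ~20 to
  ~100 genes around the same truth.
* Stepwise Cox selection by Wald p inherits all the known instabilities of
  stepwise procedures; it is provided because it is the procedure such
  studies report, not because it is recommended practice.
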