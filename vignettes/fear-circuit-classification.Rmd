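---
title: "Classifying trauma exposure from fear-circuit structural features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying trauma exposure from fear-circuit structural features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After a severe traumatic event, structural properties of the
amygdala-centred fear circuit — the amygdala itself, the orbitofrontal and
ventromedial prefrontal cortex (OMPFC), hippocampus, insula and thalamus —
change over the course of recovery from posttraumatic stress disorder
(PTSD). `fearcircuit` implements, as a tested pipeline, a multimodal
classification analysis that asks whether 23 structural summaries of these
five bilateral regions can distinguish trauma-exposed from trauma-unexposed
individuals at successive recovery stages, and which features carry the
signal.

Raw images never enter the pipeline. Its inputs are per-subject numeric
summaries of the kind produced by standard morphometry and tractography
tooling: ROI volumes and grey-matter densities, streamline counts and mean
lengths between ROI pairs, per-voxel amygdala seed-classification counts,
and covariates (age, sex, intracranial volume). Because cohorts of this
kind are rarely shareable, the package ships a synthetic-cohort generator
that emulates those tables — including the longitudinal design, attrition
and symptom trajectories — with configurable planted group differences, so
every downstream stage can be exercised and validated end to end.

## The 23 features

For each subject, `extract_features()` computes four families:

* **Local** (5 ... 1 + 4): bilateral amygdala volume (left + right, cm^3)
  and mean grey-matter density of OMPFC, hippocampus, insula, thalamus.
* **Region-wise connectivity** (10): for each ROI pair, *connection
  density* is the streamline count divided by the summed volume of the two
  ROIs (tracts/cm^3), and *connection cost* is density times mean
  streamline length (mm). Each ROI's region-wise value is the mean over
  its four incident pairs.
* **Pair-wise connectivity** (4): *relative tract strength* from the
  amygdala to each target ROI. Per amygdala voxel, the ratio of
  probabilistic samples reaching *only* that target to samples reaching
  any of the four targets; voxels with ratio below 0.01 are excluded and
  the rest averaged. Samples reaching two or more targets count in the
  denominator but in no exclusive numerator.
* **Network** (4): Latora–Marchiori global efficiency of the density
  matrix among all five ROIs and of the three induced subnetworks
  OMPFC–amygdala–hippocampus, OMPFC–amygdala–insula,
  OMPFC–amygdala–thalamus. Edges carry length 1/density; efficiency is the
  mean over ordered node pairs of the inverse shortest-path length, with
  disconnected pairs contributing zero.

Hemisphere combination follows the extensive/intensive rule: volumes and
streamline counts are summed, densities, costs, tract strengths and
grey-matter densities averaged. The efficiency network is built from
hemisphere-summed counts and volumes.

Two conventions deserve a note, as the defining texts leave them open.
First, the density-to-edge-length map: we use length = 1/density, the
standard weighted-efficiency convention for connectivity weights; binary
edges were rejected because the network is explicitly density-based.
Second, subnetwork efficiency is computed on the induced subgraph only —
paths may not route through excluded ROIs — which is what "a subnetwork of
three ROIs" means graph-theoretically. Either choice rescales but does not
reorder group contrasts here.

## Standardization

All features are adjusted for age and sex, amygdala volume additionally
for intracranial volume, by per-feature OLS fitted **on the
trauma-unexposed group only** (`fit_adjustment()`), then expressed as
Z-scores relative to the unexposed residual distribution
(`standardize()`):

    Z = (value − prediction from covariates) / reference residual SD.

Fitting the adjustment on the pooled sample would absorb genuine group
differences into the covariate slopes; the reference-group fit keeps the
Z-scale anchored to the unexposed distribution, so an exposed subject's
negative Z means a value below the unexposed mean at the same covariates.
We also Z-score the unexposed subjects themselves (the classifier needs
both groups on one scale); this is harmless because every downstream AUC
is invariant to per-feature affine maps.

## Ranking, classification and model search

`rank_features()` orders the 23 features by the absolute point-biserial
correlation with the group label (equivalently, Pearson correlation with
the 0/1 label, or the two-sample *t* statistic through
r = t/sqrt(t^2 + df)), with a stratified-bootstrap standard error
(default 5,000 resamples). Stratification preserves the group sizes;
unstratified resampling can produce single-class resamples at n = 30/29.
Ties — which essentially never occur with continuous features — break
deterministically by smaller SE, then canonical name order. SEs are
reported but do not gate selection.

`build_models()` then fits seven ridge-penalized logistic regressions on
the nested top-k subsets, k = 4..10. The fitter (`fit_ridge_logistic()`)
minimizes the penalized negative log-likelihood with unpenalized
intercept by Newton/IRLS with step-halving, so the objective is
monotonically non-increasing; convergence is score < 1e-8 or step <
1e-10 within 100 iterations. The default penalty lambda = 1e-8 is an
essentially maximum-likelihood fit that stays finite under separation;
it is configurable throughout.

AUCs use the Mann–Whitney estimator (ties half-credited), tested against
chance with a stratified percentile bootstrap (default 1,000 resamples):
one-sided p = (1 + #{AUC* <= 0.5})/(n_boot + 1), a continuity correction
that avoids p = 0. The best model (largest point AUC, ties to fewer
features) is compared with the second-best by a *paired* bootstrap — both
AUCs recomputed on the same resampled subjects — with a two-sided p from
the centred bootstrap distribution. Finally,
`individual_feature_auc()` reports each best-model feature's standalone
AUC, oriented to be at least 0.5 with the orientation recorded, since a
magnitude-only listing loses the direction of the group difference.

All stages draw their seeds from one master seed via `derive_seed(master,
tag)` (a 31-adic tag hash modulo 2^31 − 1), so any stage can be replayed
in isolation and identical seeds give byte-identical reports.

### Apparent versus cross-validated evaluation

The default evaluation is **apparent** (in-sample) AUC. At n = 30/29 with
feature selection performed on the same data, apparent AUCs of multi-
feature models are optimistic — that is a property of the protocol, not a
bug — and the per-feature AUCs and bootstrap CIs should be read in that
light. Two labelled alternatives are provided: `build_models(eval =
"loocv")` refits the ridge model per leave-one-out fold on the fixed
subsets, and `loocv_search()` additionally re-ranks features inside every
fold, the fully honest protocol. Under null (label-independent) synthetic
cohorts at the study sizes we measure: honest per-model LOOCV AUCs
average ≈ 0.46 (leave-one-out's well-known pessimism at small n), while
the maximum over the seven candidates averages ≈ 0.59 — a reminder that
*selected* AUC is an optimistic statistic under any within-sample
protocol. What is exactly chance-calibrated, and what the acceptance
suite verifies, is the AUC of a label-independent score (mean 0.500 ±
0.01 over 1,000 simulated cohorts) and the bootstrap test's type-I error
(within [0.02, 0.09] at nominal 0.05).

## The synthetic cohort generator

`generate_longitudinal()` emulates the study design: 30/25/17 exposed and
29/29/21 unexposed subjects across three imaging waves with nested
attrition (dropouts never return; dropout is random by default, with an
optional CAPS-dependent mode for sensitivity checks), covariates drawn
once per subject with age advancing between waves, CAPS symptom totals
declining 87.1 → 54.0 → 45.6 → 35.1 (SD 12.6/14.1/11.8/15.0) over
clinical times 0–3, and PTSD diagnosis counts exactly 30/30, 23/30,
12/25, 2/17.

Diagnosis is planted as a label with exact counts rather than thresholded
from CAPS: the study diagnosed by structured clinical interview, not a
CAPS cut-off, and the label-planting design makes the follow-up
arithmetic (recovery rates 23%, 52%, 88%) exactly reproducible. CAPS is
then drawn *conditionally* on the label from two shifted normals
truncated to [0, 136] (separation `caps_gap`, default 18 points), with
the within-label SD chosen so the mixture matches the configured marginal
mean and approximately the configured SD. The trade-off is explicit: this
design cannot test threshold-based diagnosis rules.

Raw summaries are drawn at physiologically sensible scales: per-hemisphere
volumes and grey-matter densities from truncated normals, streamline
counts from over-dispersed negative binomials, lengths from lognormals,
and seed-classification tables (default 200 voxels/hemisphere) from a
Dirichlet-multinomial over four exclusive-target categories plus a
"shared" remainder, with lognormal subject-level jitter of the target
weights. Mild age/sex/ICV nuisance slopes give the adjustment stage
something real to remove.

### Planting effects on the raw scale

Configured effect sizes are *standardized*: a planted effect of −1 on a
feature means the exposed group's downstream Z-score shifts by −1 in
expectation. Effects are realized on the raw-summary scale by inverting
the feature formulas, so a planted effect exercises the whole pipeline:

* amygdala volume and grey-matter densities: additive shifts (exact);
* connection densities: multiplicative streamline-count scalings on the
  incident pairs, solved by fixed point so pairs shared between two
  planted ROIs are handled jointly (exact in expectation);
* connection costs: length scalings solved the same way *given* the count
  scalings, so density-and-cost co-planting composes correctly;
* network efficiencies: uniform count scalings over the network's edge
  set (exact per subject, since efficiency is homogeneous of degree one
  in density);
* tract strengths: joint re-solve of the seed-table target weights so the
  planted targets' mean ratios shift by the required amounts.

The standardized scale for this inversion comes from an internal
calibration: `n_calibration` null subjects (default 5,000, fixed internal
seed, cached per parameter set) are generated, features extracted and the
adjustment fitted, giving each feature's reference residual SD with
relative Monte-Carlo error of about 1/sqrt(2 n) ≈ 1%.

Planting is not free of cross-talk, and the package does not pretend
otherwise: scaling counts for a density effect moves the same ROI's cost
and the network efficiencies built on those edges; tract-strength targets
are compositional, so raising one target's ratio lowers the others
slightly; and the tract-strength inversion is approximate (the 0.01
exclusion rule and voxel-level sampling bias the mean by a few percent of
an SD). Effects planted on features with disjoint raw inputs are
recovered within ±0.05–0.1 SD at large n.

Cross-talk also matters for *ranking* experiments: a planted connection
density or network efficiency drags its correlated neighbours (features
sharing streamline counts) along by a substantial fraction of the planted
effect, and at n = 30/29 those neighbours then compete with the planted
features for the ten selection slots. When the question is "are planted
features recovered in the top 10", plant on features with low mutual
cross-talk — additive local features, tract strengths, and costs (length
scalings leave counts untouched); the package's recovery checks use a
five-feature, 1-SD configuration of that kind, spanning three families,
and verify Z-recovery within ±0.15 SD and top-10 membership in over 80%
of study-sized replicates.

### What passing tests do and do not show

The generator draws waves independently given covariates (no shared
subject random effect), uses normal/NB/lognormal shapes rather than
empirical distributions, and plants clean mean shifts. Passing recovery
and calibration tests therefore demonstrates that the *pipeline* measures
what it claims on data with known structure — not that real trauma
cohorts carry these effects, nor that the study's reported AUCs (computed
on non-deposited clinical MRI data) are reproducible. Those numbers are
deliberately outside the package's acceptance surface.

## Numerical choices and problem sizes

* Bootstrap defaults: 5,000 resamples for ranking SEs, 1,000 for AUC
  inference, both stratified; percentile CIs; continuity-corrected
  p-values; all deterministic given the master seed.
* IRLS: score tolerance 1e-8, step tolerance 1e-10, 100-iteration cap,
  step-halving; non-convergence is flagged and warned, never silent.
* Degenerate inputs fail loudly and early: single-class labels,
  zero-variance features, non-positive volumes, missing pair lengths,
  infeasible diagnosis counts all raise named errors.
* Voxels with no sample reaching any target are dropped before the ratio
  (0/0); if no voxel survives the 0.01 rule the tract strength is 0 with
  a warning rather than NaN.
* The test suite scales simulations to what they measure: chance
  calibration uses 1,200 null datasets (mean-AUC tolerance 0.01 is four
  times the Monte-Carlo SE), type-I error 250 replicates, planted-effect
  recovery 8 replicates at n = 500/500 and 100 replicates at 30/29, and
  the binormal closed-form limit one cohort of 10,000 per group with a
  50-voxel seed table (the seed table is irrelevant to a volume feature's
  AUC and dominates generation cost otherwise).

## Known limitations

* Tract-strength planting accuracy degrades if planted ratios approach
  the 0.01 exclusion threshold or sum near 1 across targets.
* The apparent-evaluation default mirrors a reporting convention; it is
  not an endorsement. Use `loocv_search()` when an honest
  generalization estimate is the goal.
* The generator's attrition is non-informative by default; the
  CAPS-dependent mode implements one plausible mechanism (lower-symptom
  subjects drop out more), not a calibrated model.
* `run_timepoint()` analyses waves independently; no longitudinal
  within-subject modelling is attempted.
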