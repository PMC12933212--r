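---
title: "Methods: lesion-symptom mapping of appetite and weight change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-symptom mapping of appetite and weight change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `lesionmapr`, the
meaning of every parameter a user is likely to touch, the design of the
synthetic-cohort generator, and the numerical choices that make results
exactly reproducible. It is a methods reference, not a tutorial; see the
README for a worked example with output.

## 1. The scientific question and the data model

The package asks whether chronic appetite change and weight change after a
focal brain lesion are associated with damage to specific brain locations.
The raw materials are:

* one **binary lesion mask** per subject on a shared voxel grid
  (`lesion_mask()`, `read_lesion_mask()`; NIfTI I/O through `RNifti`);
* **behavioural records**: dated BDI-II appetite-item responses
  (`subject_id`, `day_offset`, `item18_code`, `bdi_total`) and dated weight
  measurements (`subject_id`, `day_offset`, `weight_kg`).

Masks are assembled into a subjects-by-voxels matrix (`stack_cohort()`),
and voxel order is R's column-major array order throughout, so a linear
voxel index always means the same location in every map the package
produces.

## 2. Outcome construction

**Appetite.** BDI-II item 18 has seven response options: `0` and pairs
`1a/1b`, `2a/2b`, `3a/3b` of increasing severity, where the `a` member of
each pair describes appetite *decrease* and the `b` member *increase*.
`recode_appetite()` maps them to a signed ordinal score −3..+3. A subject's
chronic score is taken from assessments at least `chronic_min_days` (default
90) days post-lesion; when several qualify, the one with the largest
absolute score is used (earliest assessment breaking ties), on the rationale
that the analysis targets the presence of a lasting change, not its average.
Subjects with no chronic assessment are excluded and reported.

**Weight.** `weight_changes()` selects, per subject, a baseline W1 — the
measurement closest in absolute days to lesion onset among those no later
than `w1_max_day` (default 90; pre-lesion measurements qualify) — and a
follow-up W2 — the latest measurement in `[w2_min_day, w2_max_day]`
(defaults 90 and 1000) at least `min_gap_days` (default 30) after W1. The
selection provably finds a pair whenever any valid pair exists (the unit
tests check this against an exhaustive pair search). Per-cent change is
`100 * (W2 - W1) / W1`; `binarize_weight_change()` maps its sign to the
loss (−1) / gain (+1) groups, excluding exact zeros by default
(`zero_change = "gain"` reassigns them). `clinically_significant()`
restricts to |change| above a threshold (default 5%).

## 3. Lesion features: minimum overlap and DTLVC

Voxels lesioned in fewer than `k` subjects (default 10 for the appetite
analysis, 2 for the smaller weight cohorts) carry almost no information and
inflate the multiple-comparison burden; `min_overlap_filter()` removes
them. Lesion volume is a powerful confound: large lesions damage more
voxels *and* cause more symptoms of every kind. Direct total lesion volume
control (DTLVC, `dtlvc_transform()`) divides each subject's mask by the
square root of their lesion volume, giving every full-grid row unit sum of
squares. The filter is applied *after* scaling, so in-mask row energy is at
most 1 and each nonzero entry is exactly `1/sqrt(total lesion volume)`.

## 4. Multivariate mapping: PLSR with permutation and bootstrap

`plsr_map()` fits partial least squares regression of the signed appetite
score on the DTLVC features using the SIMPLS algorithm for a single
response. For univariate outcomes SIMPLS is deterministic — each score
direction is the current deflated covariance vector `X'y` — so there is no
sign ambiguity. The back-projected coefficients form the voxel weight map:
negative weights mark damage associated with decreased appetite.

The component count can be fixed (`n_components`) or chosen by 5-fold
cross-validated predictive R² (`select_n_components()`), falling back to 1
when nothing beats the outcome mean. Inference has three layers:

* **Whole-map permutation test** (`permute_model_fit()`): the outcome is
  permuted `n_permutations` (default 1000) times, the model refit, and the
  p-value is the add-one estimate `(1 + #{null R² ≥ observed}) / (B + 1)`,
  which can never be zero and is exact at finite B.
* **Bootstrap voxel z** (`bootstrap_voxel_stats()`): subjects are resampled
  with replacement `n_bootstrap` (default 1000) times; each voxel's z is
  its observed weight divided by the bootstrap SD of that weight
  (streaming mean/SS, O(V) memory). Voxels with zero bootstrap variance are
  flagged and set to z = 0 instead of producing infinities. The same
  resamples yield a percentile CI for the in-sample R².
* **FWE voxel tests**: by default Holm correction of two-sided
  normal-theory p-values of the bootstrap z at `alpha_fwe` (default 0.05).
  A permutation max-|z| alternative (`fwe_method = "perm_maxz"`) is
  available behind the configuration for users who prefer a fully
  permutation-based family-wise bound; it standardizes permuted refits by
  the observed bootstrap SDs.

An independent oracle validates the implementation: PLS1 with k components
equals ordinary least squares restricted to the Krylov space
`span{X'y, (X'X)X'y, ...}`; the test suite checks coefficient equality to
machine precision for 1–4 components.

## 5. Mass-univariate mapping: proportional subtraction with continuous FWE

`prop_diff_map()` computes, per analysis-mask voxel, the lesion proportion
among weight-gain subjects minus that among weight-loss subjects,
`D = p(+1) − p(−1) ∈ [−1, 1]`. Group labels are permuted
(`n_permutations`, default 1000, preserving group sizes) and each
permutation contributes the `voxel_extent`-th largest |D| (default 1000;
`voxel_extent = 1` recovers the classical max-statistic test). All
permutations are evaluated in a single `V' × N` by `N × B` matrix product.
The critical value is the `ceiling((1 − alpha)(B + 1))`-th order statistic
of that null.

**Tie handling.** D is lattice-valued — every value is an integer divided
by `n_gain * n_loss` — so exact ties between observed and permuted values
are routine, and a naive "≥ quantile" cut is anticonservative (in null
prototypes it rejected at roughly twice the nominal level). Two choices
follow. First, observed and permuted maps are both computed as exact
integer numerators over the common denominator, so a tie in exact
arithmetic is a tie in floating point. Second, survivors and the extent
verdict use the exact add-one corrected p-value
`(1 + #{b: vth-largest_b ≥ stat}) / (B + 1) ≤ alpha`, which counts ties
toward the null and stays valid under ties; without ties it coincides with
thresholding at the reported critical value. The default extent rule counts
all surviving voxels on the map (`extent_rule = "global"`); a
26-connectivity largest-cluster variant (`"cluster"`) is available.
Uncorrected add-one voxel p-values are reported for survivors.

## 6. Confound analyses

`run_confound_regressions()` screens covariates with simple Pearson
regressions (pairwise deletion, per-covariate n). `residualize()` removes a
covariate from the outcome by OLS — used to re-run the appetite analysis
with depression severity (BDI total minus the appetite item) regressed out —
and `spatial_correlation()` quantifies how similar the resulting weight
maps are.

## 7. The synthetic-cohort generator

`simulate_cohort()` produces cohorts with known ground truth:

* **Lesions** are single 6-connected components grown by random
  neighbour accretion from a seed voxel to a volume drawn uniformly from
  `volume_range`. Seeds come from a centre-biased Gaussian prior (or any
  user density), reproducing the key realism property of registry cohorts:
  overlap concentrates in well-covered central territory while the
  periphery stays sparse. Accretion keeps a flat candidate list with a
  membership flag, so growth is O(1) per voxel.
* **Outcomes** follow the same mechanism the analyses assume: the latent
  outcome is `−effect_size * load + noise`, where `load` is the subject's
  DTLVC-scale lesion load on a configurable `truth_region` (default a
  central ball). Appetite discretizes the latent value at symmetric cut
  points ±0.5, ±1.5, ±2.5 into −3..+3 and emits raw item-18 codes with
  chronic-phase day offsets; weight emits two dated measurements whose
  per-cent change equals the latent value (clamped above −80%).

**Realism limits.** Lesions are isotropic blobs without vascular-territory
anatomy; outcomes depend on truth-region load only (no network effects, no
comorbidity structure); appetite noise is Gaussian on the latent scale
rather than ordinal measurement error; and day offsets are uniform. The
generator is built for calibration and recovery benchmarking, not for
simulating clinically realistic effect sizes.

## 8. Determinism and numerical choices

Every stochastic routine takes a `seed` and derives independent substreams
with a Lehmer map (`derive_seed()`): permutation, bootstrap, CV folds and
the max-z null use distinct streams per master seed, and each simulated
subject has its own substream — enlarging a cohort never reshuffles
earlier subjects. Identical configuration and seed give byte-identical
NIfTI maps and JSON reports (verified by checksum in the tests). Add-one
p-value estimators are used everywhere a permutation or bootstrap null is
finite. JSON is written with `digits = NA` (full precision); NIfTI headers
carry the grid affine with sform/qform code 2.

## 9. Limitations

* In-sample PLSR R² is an optimistic fit measure; the permutation test
  calibrates it, but out-of-sample prediction is not the target.
* Holm correction on bootstrap z assumes approximate normality of the
  bootstrap distribution of voxel weights; the permutation max-|z| option
  avoids this at higher cost.
* The continuous-FWE extent criterion controls the family-wise error of
  the *extent* claim; individual survivor voxels below the extent are
  exploratory and carry only uncorrected p-values.
* Mass-univariate proportional subtraction inherits the usual VLSM spatial
  bias toward well-covered voxels; the minimum-overlap filter mitigates
  but does not remove it.
* With ordinal outcomes and small cohorts, bootstrap resamples can have
  constant outcomes; such resamples are redrawn, which slightly biases the
  bootstrap toward more variable subsets in tiny samples.

## 10. End-to-end entry points

```{r}
report <- run_appetite_analysis(masks, behaviour, k = 10,
                                n_permutations = 1000, n_bootstrap = 1000,
                                residualize_bdi = TRUE, seed = 1,
                                output_dir = "out/appetite")
wreport <- run_weight_analysis(masks, weights_table, k = 2,
                               n_permutations = 1000, voxel_extent = 1000,
                               clinical_subset = TRUE, seed = 1,
                               output_dir = "out/weight")
```

Both return an `lsm_report` carrying the fitted map object, a one-row
`glance()` summary, full subject accounting (raw → chronic-scored →
analysed, with excluded ids), the configuration and the seed; with
`output_dir` they also write NIfTI maps and `report.json`.
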