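---
title: "Methods: radiomic phenotyping of the tumor microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic phenotyping of the tumor microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radtme` implements a radio-genomics analysis that asks whether quantitative
imaging phenotypes of a breast lesion on DCE-MRI carry information about the
cellular composition of its microenvironment. This vignette is the package's
own account of the models and procedures, the tunable parameters, the
synthetic cohorts used to exercise them, and the design choices made where
the design was genuinely open.

## The pipeline

Six stages, each behind an exported function:

1. **Simulation** (`gen_cohort`) — paired imaging + expression cohorts with
   planted ground truth.
2. **Feature extraction** (`extract_features`) — a fixed catalog of 199
   radiomic features per lesion: 111 static and 88 kinetic.
3. **Abundance scoring** (`score_abundance`, `stratify_median`) — marker-mean
   scores for 10 immune/stromal cell populations, median high/low labels.
4. **Association scan** (`univariate_scan`, `correlation_matrix`,
   `feature_group_ttests`) — per-pair simple regression with BH FDR control.
5. **Classification** (`rfe_select`, `fit_classifier`, `loocv_eval`,
   `external_eval`) — per-population high/low prediction with RFE feature
   selection, binary logistic gradient boosting, pooled leave-one-out ROC,
   and an unchanged-model external test.
6. **Batch diagnostic** (`pca_batch_check`) — PCA + silhouette of the
   institution labels.

## Kinetic model

Each lesion study holds one pre-contrast and three post-contrast volumes at
times $t_0 < t_1 < t_2 < t_3$ (minutes). Per voxel, the relative enhancement
is

$$E_t = \frac{S_t - S_0}{\max(S_0, \varepsilon)}, \qquad E_0 = 0,$$

with a baseline guard $\varepsilon$ (default 1 intensity unit) so
non-positive baselines never divide by zero. The semi-quantitative
parameters are $PE = \max_t E_t$ (peak enhancement), $TTP$ (time of the
first maximizer, minus $t_0$), $WIS = PE/TTP$ (wash-in slope, min$^{-1}$)
and $WOS = (E_3 - E_{peak})/(t_3 - t_{peak})$ when the peak precedes the
last phase, else 0. Flat curves are assigned the first post-contrast phase
with $WIS = 0$; ties are broken toward the earliest maximizer. Enhancement
is baseline-relative because that is the standard unit-free normalization in
semi-quantitative DCE analysis; the parameters are computed per voxel and
then aggregated (a single tumor-mean-curve variant can be obtained by
averaging phases before `voxel_kinetics`, but the per-voxel route is what
the heterogeneity features require).

With three post-contrast phases, $TTP$ takes exactly three values, so the
**TTP characteristic map** partitions in-mask voxels into quick /
intermediate / slow arrivals without any clustering algorithm; for longer
series the same operation could be re-backed by k-means on TTP (k = 3)
without changing its interface.

The 88 kinetic features split into:

* **aggregate (10)** — mean and SD of WIS, WOS, PE, TTP; the maximum PE
  (MPE); the hot spot, i.e. the highest mean PE over any in-mask
  3×3×3 (26-connected) neighbourhood. The neighbourhood size is a fixed
  convention; "connected voxels" admits many readings and 26-connectivity
  at radius 1 is the smallest isotropic one.
* **heterogeneity (21)** — per TTP sub-cluster, mean and SD of WIS, WOS, PE
  plus the sub-cluster proportion. Empty sub-clusters contribute zeros
  rather than NaN so the catalog stays rectangular.
* **textural-kinetic (57)** — 19 descriptors per parameter map (WIS, WOS,
  PE): 13 classic co-occurrence statistics, the absolute value of
  differences (AVD), and 5 histogram statistics. The maps are quantized
  in-mask to 11 equal-width levels (matching the static level count under
  8-bit/bin-width-25 discretization) and the co-occurrence matrix is
  symmetric, normalized and averaged over the 13 unique distance-1 3D
  offsets. Texture is computed on the WIS/WOS/PE maps — a 3-level label map
  alone cannot support 57 distinct descriptors — with the TTP map's
  structure entering through the partition-driven heterogeneity group.

## Static radiomics

The 111 static features are shape (14), first-order intensity (22) and five
gray-level matrix families (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5).
The per-family split is a frozen, documented catalog; the binding constraint
is the total of 111 and the family membership, both enforced by the
constructors. Intensity and texture families are computed on the first
post-contrast phase (highest lesion conspicuity), rescaled in-mask to 8 bits
and quantized with a fixed bin width of 25 (at most ⌈256/25⌉ = 11 levels);
the per-phase tumor mean intensities are separate catalog entries.

Shape descriptors are computed in physical units. The mesh surface area and
mesh volume come from a marching-tetrahedra isosurface (Kuhn 6-tetrahedron
decomposition, conforming across cubes) of the mask indicator mollified
with a 3×3×3 box filter; vertex positions are linearly interpolated at the
0.5 level. Mollification matters: a midpoint staircase surface
overestimates a digital ball's area by ~28%, while the mollified surface is
within ~2% (sphericity 0.99 for a radius-10 ball). Masks so thin that they
vanish under mollification fall back to the binary midpoint surface, and a
single-voxel mask uses the voxel cuboid closed forms. Axis lengths are
$4\sqrt{\lambda_i}$ from the PCA of in-mask voxel coordinates; elongation
and flatness are the corresponding ratios.

Texture matrices are built in 3D: GLCM over the 13 distance-1 offsets
(symmetric, matrix-averaged), GLRLM over the same 13 directions
(feature-averaged), GLSZM/GLDM/NGTDM over the 26-neighbourhood. GLDM
dependence counts the voxel itself plus its equal-level neighbours
(α = 0), so the dependence index starts at 1 and size-weighted formulas
never divide by zero. Degenerate single-level ROIs take closed-form values
(joint energy 1, contrast 0, correlation defined as 0), never NaN. Every
family is validated against exhaustive-enumeration oracles in the test
suite.

## Abundance scoring and stratification

The score of population $k$ in sample $j$ is the arithmetic mean of
$\log_2(1 + \text{count})$ over $k$'s marker genes — marker-mean scoring in
the MCP-counter style, on the log scale because marker expression is
log-normal-like and the arithmetic mean of logs is robust to single
high-expression outliers. The shipped marker sets are synthetic-compatible
placeholders (5 genes per population, matching the generator); any
two-column (population, gene) TSV can be substituted via `read_markers`,
e.g. published marker lists.

Samples are labelled **high** when their score is ≥ the median score of
that population *over the dataset being labelled* — so an external cohort
is stratified against its own medians, not the training medians. The
original analysis is ambiguous on this point ("across the entire data
set"); own-median stratification was chosen because it keeps the external
label definition self-contained and balanced. With ties at the median the
high group can exceed half; all-equal scores give an all-high population,
which downstream classification refuses as single-class.

## Association scan

For each of the 199 × 10 pairs, the abundance is regressed on the feature;
the two-sided t-test on the slope is algebraically identical to the Pearson
correlation test, and both the slope (abundance per feature unit) and $r$
are reported. The BH family is all pairs jointly by default — the more
conservative choice when the original family is unknown — with
per-population adjustment available by flag. Zero-variance features are
annotated and excluded from the family rather than silently dropped. The
high/low contrast t-tests (tumor volume and mean PE against each
population's labels, BH-adjusted per feature) use the Welch unequal-variance
form, the safer default when only "two-sided t-tests" is specified.

## Classification

RFE follows the standard backward scheme: within each of 5×5
repeated CV folds a random forest (200 trees) ranks features by importance;
each candidate size (default 2–20, spanning the 3–16 range typically
selected) keeps the fold's top-k subset and records held-out accuracy; the
best mean-accuracy size wins with ties to the smaller size, and the final
set is the full-data top-k. Selection is run once on the training cohort
and LOOCV is then run on the selected features — matching a single
per-model feature count — which leaks the selection step into the
cross-validation; the evaluation record states this mode
(`rfe_outside_loocv`), and nesting selection inside each fold is possible
by calling `rfe_select` per fold.

The classifier is binary logistic gradient boosting (xgboost): 100 rounds,
depth 3, learning rate 0.1, single-thread, fixed seed — unstated in the
original and therefore fixed here as conventional defaults, overridable per
call. LOOCV pools all n held-out scores into one ROC (per-fold ROC is
undefined for a single sample); AUC uses midrank tie handling, equal to the
Mann–Whitney pair-count statistic. The permutation null re-runs the full
LOOCV on permuted labels with lighter boosting settings (30 rounds, depth
2) since the null's center is hyperparameter-free; its mean sits at 0.5
when the pipeline does not leak labels.

## The synthetic cohorts

The generator defines the study conditions under which everything is
tested. Lesions are random-axis ellipsoids (≥ 30 voxels) on desk-scale
grids; defaults mirror the two-institution geometry at reduced resolution —
profile A "axial-like" 14×32×32 voxels at 2.0×0.7×0.7 mm, profile B
"sagittal-like" 14×24×24 at 2.2×0.9×0.9 mm with a fixed affine intensity
shift (×1.12 + 18), which is what makes cross-institution batch structure
recoverable. Acquisition times default to 0, 1, 2, 3 minutes; no timing
protocol is stated for the original acquisitions, so phantom timing is a
free parameter.

Each in-mask voxel draws one of three enhancement archetypes (quick /
intermediate / slow, default fractions 0.4/0.3/0.3) and follows a
piecewise-linear curve: rise from baseline 100 to the archetype's peak
(levels 1.2/1.0/0.85, peak phases 1/2/3, washout 0.25/0.15/0 min⁻¹), plus
Gaussian noise (SD 2). Piecewise-linear rather than pharmacokinetic
(Tofts-type) curves are deliberate: every kinetic parameter then has a
closed form, giving exact oracles — noiseless phantoms must reproduce every
aggregate and heterogeneity feature to 1e-9 relative tolerance.

Expression matrices are 2,000 genes (a desk-scale stand-in for a
20,530-gene transcriptome) with 5 markers per population:
$\log_2(1+\text{count}) = \mu_g + a_{jk} + \epsilon$ for markers (slope 1,
noise SD 0.25) and abundance-free background otherwise. Planted
associations run through a Gaussian copula: one latent amplitude per lesion
scales all archetype peaks, and the target population's true abundance is
correlated with that latent at the requested $r$; the realized correlation
is recorded in the ground truth rather than assumed. Large-n statistical
checks (n = 500 planted-association recovery, n = 60 classification
cohorts) use 12×16×16 grids so lesions stay a few hundred voxels; catalog
and oracle checks use the full-size default profiles.

What the generator does **not** emulate: breast anatomy and surrounding
parenchyma (masks are exact, so segmentation error is out of scope),
pharmacokinetic nonlinearity, spatially structured sub-clusters (archetypes
are drawn i.i.d. per voxel, so textural-kinetic features see salt-and-pepper
texture rather than regional heterogeneity), scanner-specific noise spectra,
and real marker biology. Passing tests therefore demonstrate computational
correctness and statistical calibration under known ground truth — not
clinical validity on real cohorts, whose headline correlations and AUCs
depend on data this package does not ship.

## Numerical conventions

* Co-occurrence and probability matrices are normalized to sum 1 (±1e-12);
  offsets with no valid pair are skipped from the average.
* Degenerate inputs never produce NaN: constant ROIs quantize to one level,
  empty sub-clusters contribute zeros, single-voxel masks have zero axis
  lengths and SDs.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  and per-lesion seeds are derived from the cohort seed, so cohorts are
  reproducible byte-for-byte.
* CSV round trips keep 17 significant digits.

## Known limitations

* The per-family feature splits (shape 14 / first-order 22 / GLCM 24 /
  GLRLM 16 / GLSZM 16 / GLDM 14 / NGTDM 5, and 10/21/57 on the kinetic
  side) are reconstructions; only the totals of 111 and 88 are externally
  fixed. The catalog is frozen so counts are enforceable.
* RFE outside LOOCV is optimistic; the strict nested mode is exposed but
  not the default, to match the single selected-feature-set design.
* Marker sets are synthetic; real analyses must supply their own.
* `pca_batch_check` reports only the top-2-component silhouette; subtler
  batch structure in lower components is not flagged.
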