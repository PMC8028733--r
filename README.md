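# radtme — radiomic phenotyping of the breast tumor microenvironment

`radtme` is an R implementation of a radio-genomics analysis linking breast
DCE-MRI radiomic phenotypes to the cellular composition of the tumor
microenvironment (TME). It is written for imaging/genomics analysts who want
the full pipeline — feature extraction, cell-abundance scoring, association
scanning, and predictive modeling — as tested, reusable functions, exercised
end to end on synthetic cohorts with planted ground truth.

## What it computes

**Radiomics.** Each lesion study (one pre-contrast volume, three
post-contrast volumes, a binary tumor mask) yields a fixed catalog of 199
features:

* **111 static features** — shape (14; mesh surface/volume, sphericity,
  axis lengths, ...), first-order intensity (22, including the per-phase
  tumor mean intensities), and five 3D gray-level texture families (GLCM 24,
  GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5), computed after in-mask 8-bit
  rescaling and fixed bin-width quantization (binWidth = 25).
* **88 kinetic features** — from the per-voxel relative enhancement
  E_t = (S_t − S_0)/max(S_0, ε): peak enhancement PE = max E_t, time to
  peak TTP, wash-in slope WIS = PE/TTP, wash-out slope
  WOS = (E_last − E_peak)/(t_last − t_peak). Three groups: aggregate (10,
  with maximum PE and the hot spot — the highest neighbourhood-mean PE);
  heterogeneity (21, per-sub-cluster statistics of the 3-label TTP
  characteristic map partitioning voxels into quick/intermediate/slow
  arrivals); textural-kinetic (57, co-occurrence and histogram descriptors
  of the quantized WIS/WOS/PE maps).

**TME abundance.** Ten cell populations (CD3+ T cells, CD8+ T cells,
cytotoxic lymphocytes, NK cells, B lineage, monocytic lineage, myeloid
dendritic cells, neutrophils, endothelial cells, fibroblasts) are scored as
the mean log2(1 + count) over marker genes (MCP-counter-style), then
median-stratified into high/low per population (score ≥ median → high).

**Statistics and modeling.** A univariate scan fits abundance ~ feature for
all 199 × 10 pairs with Benjamini–Hochberg FDR control; per-population
classifiers (recursive feature elimination by random-forest importance +
binary logistic gradient boosting) are evaluated by pooled leave-one-out
ROC/AUC and by an unchanged-model external test, with a PCA/silhouette
diagnostic for cross-institution batch structure.

The synthetic generator produces paired imaging + expression cohorts:
piecewise-linear enhancement phantoms (closed-form kinetics), two
institution profiles with differing grid/spacing and a fixed intensity
shift, and Gaussian-copula-planted feature–abundance correlations whose
realized values are recorded in the ground truth.

## Worked example

```r
library(radtme)

cfg <- cohort_config(n_lesions = 12, seed = 7,
                     planted_assoc = list(list(feature = "kin_agg_pe_mean",
                                               population = "fibroblasts",
                                               r = 0.8)))
cohort <- gen_cohort(cfg)

fv <- extract_features(cohort$studies[[1]])
length(fv)
#> [1] 199
round(fv[c("shape_voxel_volume", "fo_mean_post1", "glcm_contrast",
           "kin_agg_pe_mean", "kin_het_quick_prop")], 3)
#> shape_voxel_volume      fo_mean_post1      glcm_contrast    kin_agg_pe_mean
#>            917.280            209.922             32.818              1.620
#> kin_het_quick_prop
#>              0.381
```

The first lesion occupies 917 mm³, its mean first-post-contrast intensity is
210, and 38% of its voxels reach peak enhancement at the first post-contrast
phase; its voxel-mean peak enhancement is 1.62 (162% above baseline).

```r
ab <- stratify_median(score_abundance(cohort$expression))
round(ab$scores[1:3, c("fibroblasts", "nk_cells")], 2)
#>      fibroblasts nk_cells
#> A001       11.46     9.55
#> A002        8.30    10.34
#> A003        9.24     9.17

feats <- feature_table(cohort$studies)
res <- univariate_scan(feats, ab)
subset(res, feature == "kin_agg_pe_mean" & population == "fibroblasts")
#>              feature  population        r            p       p_adj
#> 1907 kin_agg_pe_mean fibroblasts 0.893853 8.858633e-05 0.007107207
```

Even at n = 12 the planted mean-PE/fibroblast coupling (target r = 0.8)
surfaces with an estimated r of 0.89 and survives FDR adjustment over all
1,990 pair tests.

## The analysis workflow

`analysis/` contains the numbered drivers that run the study end to end on
synthetic two-institution cohorts (43 axial-profile training lesions, 30
sagittal-profile external lesions), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohorts + ground truth
Rscript analysis/02_extract_features.R  # 199-column feature tables
Rscript analysis/03_score_abundance.R   # 10-population scores + labels
Rscript analysis/04_association.R       # 1,990-row scan, heatmap matrix, t-tests
Rscript analysis/05_classification.R    # per-population LOOCV + external AUC
Rscript analysis/06_batch_diagnostic.R  # PCA silhouette of the two profiles
```

`run_full()` performs the same sequence as a single call.

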