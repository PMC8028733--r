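#!/usr/bin/env Rscript
# Stage 1 — simulate the paired imaging + expression cohorts.
#
# Two cohorts mirror the two-institution design: 43 axial-profile lesions
# (training) and 30 sagittal-profile lesions (external test), with a
# fibroblast/mean-PE association planted at r = 0.5 so downstream stages
# have a recoverable target. Ground truth is kept alongside the data.

suppressPackageStartupMessages(library(radtme))
dir.create("results", showWarnings = FALSE)

plant <- list(list(feature = "kin_agg_pe_mean", population = "fibroblasts",
                   r = 0.5))
train_cfg <- cohort_config(n_lesions = 43, institution_profile = "A",
                           planted_assoc = plant, seed = 101)
test_cfg <- cohort_config(n_lesions = 30, institution_profile = "B",
                          planted_assoc = plant, seed = 202)

train <- gen_cohort(train_cfg)
test <- gen_cohort(test_cfg)

cat(sprintf("training cohort: %d lesions (profile A), realized planted r = %.3f\n",
            length(train$studies), train$truth$realized_r))
cat(sprintf("external cohort: %d lesions (profile B), realized planted r = %.3f\n",
            length(test$studies), test$truth$realized_r))

# example NIfTI export of the first training lesion (the on-disk interface)
dir.create("results/nifti_example", showWarnings = FALSE)
paths <- write_study(train$studies[[1]], "results/nifti_example/lesion_A001")
cat("wrote example NIfTI study:", basename(paths[1]), "...\n")
write_markers(default_marker_sets(), "results/markers.tsv")

saveRDS(list(train = train, test = test,
             train_cfg = train_cfg, test_cfg = test_cfg),
        "results/cohorts.rds")
cat("saved cohorts to results/cohorts.rds\n")
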