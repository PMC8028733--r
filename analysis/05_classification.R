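#!/usr/bin/env Rscript
# Stage 5 — per-population high/low classification.
#
# For each cell population: RFE feature selection on the training cohort,
# a binary logistic gradient-boosting model, pooled leave-one-out ROC/AUC,
# and an unchanged-model external test on the second-institution cohort.

suppressPackageStartupMessages(library(radtme))
feats <- read_table("results/features_train.csv")
feats_test <- read_table("results/features_test.csv")
ab <- readRDS("results/abundance.rds")

evals <- list()
for (pop in cell_populations()) {
  y <- ab$train$labels[rownames(feats), pop]
  sel <- suppressWarnings(rfe_select(feats, y, seed = 303))
  cv <- loocv_eval(feats[, sel, drop = FALSE], y, seed = 303)
  model <- fit_classifier(feats[, sel, drop = FALSE], y, seed = 303)
  ext <- external_eval(model, feats_test[, sel, drop = FALSE],
                       ab$test$labels[rownames(feats_test), pop])
  evals[[pop]] <- data.frame(population = pop, n_selected = length(sel),
                             loocv_auc = cv$auc, external_auc = ext$auc)
  cat(sprintf("%-24s %2d features  LOOCV AUC %.2f  external AUC %.2f\n",
              pop, length(sel), cv$auc, ext$auc))
}
res <- do.call(rbind, evals)
cat(sprintf("selected feature counts span %d-%d; mean LOOCV-to-external drop %.3f\n",
            min(res$n_selected), max(res$n_selected),
            mean(res$loocv_auc - res$external_auc)))
utils::write.csv(res, "results/model_evals.csv", row.names = FALSE)
cat("wrote results/model_evals.csv\n")
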