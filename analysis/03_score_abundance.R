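#!/usr/bin/env Rscript
# Stage 3 — cell-population abundance scoring and high/low stratification.
#
# Marker-mean scores for the 10 immune/stromal populations, then per-cohort
# median stratification (each cohort is labelled against its own medians).

suppressPackageStartupMessages(library(radtme))
ch <- readRDS("results/cohorts.rds")

ab_train <- stratify_median(score_abundance(ch$train$expression))
ab_test <- stratify_median(score_abundance(ch$test$expression))

cat(sprintf("scored %d populations on %d train and %d test samples\n",
            ncol(ab_train$scores), nrow(ab_train$scores),
            nrow(ab_test$scores)))
# sanity against ground truth: score/abundance correlation per population
r_truth <- vapply(cell_populations(), function(p)
  cor(ab_train$scores[, p], ch$train$truth$abundance[, p]), numeric(1))
cat(sprintf("score vs true abundance r: min %.2f, median %.2f\n",
            min(r_truth), median(r_truth)))

write_table(ab_train$scores, "results/abundance_train.csv")
write_table(ab_test$scores, "results/abundance_test.csv")
saveRDS(list(train = ab_train, test = ab_test), "results/abundance.rds")
cat("wrote results/abundance_{train,test}.csv\n")
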