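#!/usr/bin/env Rscript
# Stage 4 — univariate association scan, correlation heatmap matrix, and the
# volume / mean-PE high-low t-tests.
#
# Every (feature, population) pair gets a simple linear regression with a
# BH-adjusted p-value (one family over all pairs). On the training cohort
# the planted fibroblast coupling should surface among the top hits.

suppressPackageStartupMessages(library(radtme))
feats <- read_table("results/features_train.csv")
ab <- readRDS("results/abundance.rds")$train

scan <- suppressWarnings(univariate_scan(feats, ab))
cat(sprintf("association scan: %d pair tests (%d skipped as zero-variance)\n",
            nrow(scan), sum(scan$note == "zero_variance")))
sig <- scan[!is.na(scan$p_adj) & scan$p_adj < 0.05, ]
sig <- sig[order(sig$p_adj), ]
cat(sprintf("%d pairs significant at FDR 0.05; top hits:\n", nrow(sig)))
print(utils::head(sig[, c("feature", "population", "r", "p_adj")], 5),
      row.names = FALSE)

cm <- suppressWarnings(correlation_matrix(feats, ab))
tt <- feature_group_ttests(feats, ab)
cat("volume / mean-PE t-tests (BH-adjusted within feature):\n")
print(tt[tt$p_adj < 0.05, c("feature", "population", "t", "p_adj")],
      row.names = FALSE)

utils::write.csv(scan, "results/associations.csv", row.names = FALSE)
write_table(cm, "results/correlation_matrix.csv")
utils::write.csv(tt, "results/group_ttests.csv", row.names = FALSE)

# basic heatmap rendering of the correlation structure
grDevices::pdf("results/correlation_heatmap.pdf", width = 7, height = 10)
pheatmap_ok <- requireNamespace("pheatmap", quietly = TRUE)
if (pheatmap_ok) {
  pheatmap::pheatmap(cm, cluster_rows = FALSE, cluster_cols = FALSE,
                     show_rownames = FALSE,
                     main = "feature vs population correlation")
} else {
  graphics::image(t(cm), main = "feature vs population correlation")
}
grDevices::dev.off()
cat("wrote results/associations.csv, correlation_matrix.csv, group_ttests.csv\n")
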