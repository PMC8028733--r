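#' Extract the full 199-feature vector of one lesion
#'
#' @param study A [dce_study()].
#' @param bits,bin_width Static quantization settings (defaults 8, 25).
#' @param levels Kinetic-texture quantization levels (default 11).
#' @return Named numeric vector of 199 values in catalog order.
#' @export
extract_features <- function(study, bits = 8, bin_width = 25, levels = 11L) {
  c(static_feature_vector(study, bits, bin_width),
    kinetic_feature_vector(study, levels))
}

#' Feature table of a cohort
#'
#' @param studies List of [dce_study()] objects.
#' @param ... Passed to [extract_features()].
#' @return Lesions x 199 matrix, rownames = lesion IDs.
#' @export
feature_table <- function(studies, ...) {
  rows <- vapply(studies, extract_features, numeric(199), ...)
  t(structure(rows, dimnames = list(feature_catalog(),
                                    vapply(studies, `[[`, "", "lesion_id"))))
}

#' Kinetic-only feature table
#'
#' Used where the downstream question involves only the 88 kinetic features
#' (large simulated cohorts).
#'
#' @inheritParams feature_table
#' @return Lesions x 88 matrix.
#' @export
kinetic_feature_table <- function(studies, ...) {
  rows <- vapply(studies, kinetic_feature_vector, numeric(88), ...)
  t(structure(rows, dimnames = list(kinetic_feature_catalog(),
                                    vapply(studies, `[[`, "", "lesion_id"))))
}

#' Numeric table round trip
#'
#' CSV writers/readers that preserve values to near machine precision and
#' column order.
#'
#' @param x Numeric matrix or data frame with row and column names.
#' @param path CSV path.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  df <- cbind(id = rownames(df),
              as.data.frame(lapply(df, function(col)
                if (is.numeric(col)) format(col, digits = 17, trim = TRUE)
                else col), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @return `read_table()`: numeric matrix with rownames from the `id`
#'   column.
#' @export
read_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}

#' Run the full synthetic radio-genomics pipeline
#'
#' Orchestrates every stage on generated cohorts: simulate a training and an
#' external cohort, extract the 199-feature table per lesion, score and
#' median-stratify the 10 cell populations, run the univariate FDR scan and
#' the correlation matrix, fit per-population RFE + boosting models with
#' LOOCV and external evaluation, and run the PCA batch diagnostic. Each
#' stage writes its CSV/JSON artifact under `out_dir` and appends one log
#' line with row counts.
#'
#' @param train_config,test_config [cohort_config()]s for the training
#'   (LOOCV) and external cohorts.
#' @param out_dir Output directory (created if needed).
#' @param rfe_sizes,hyper Selection sizes and boosting settings.
#' @param seed Integer seed for the modeling stages.
#' @param populations Populations to model (default all 10).
#' @return Invisibly, a list with `features`, `features_test`, `abundance`,
#'   `abundance_test`, `scan`, `cormat`, `ttests`, `evals` (per-population
#'   records), `batch`.
#' @export
run_full <- function(train_config, test_config, out_dir,
                     rfe_sizes = c(2, 3, 4, 6, 8, 10, 12, 16, 20),
                     hyper = list(), seed = 1L,
                     populations = cell_populations()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(..., "\n", file = logf, append = TRUE, sep = "")
  cat("radtme run_full; seed=", seed, "; config hash=",
      sum(utils::object.size(train_config)), "\n", file = logf, sep = "")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  train <- stage("simulate", gen_cohort(train_config))
  test <- stage("simulate", gen_cohort(test_config))
  log_line("simulate: ", length(train$studies), " train + ",
           length(test$studies), " test lesions")

  feats <- stage("extract", feature_table(train$studies))
  feats_test <- stage("extract", feature_table(test$studies))
  write_table(feats, file.path(out_dir, "features_train.csv"))
  write_table(feats_test, file.path(out_dir, "features_test.csv"))
  log_line("extract: ", nrow(feats), " x ", ncol(feats), " feature table")

  ab <- stage("score", stratify_median(score_abundance(train$expression)))
  ab_test <- stage("score", stratify_median(score_abundance(test$expression)))
  write_table(ab$scores, file.path(out_dir, "abundance_train.csv"))
  write_table(ab_test$scores, file.path(out_dir, "abundance_test.csv"))
  log_line("score: ", nrow(ab$scores), " x ", ncol(ab$scores),
           " abundance table")

  scan <- stage("associate", univariate_scan(feats, ab))
  utils::write.csv(scan, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)
  cm <- stage("associate", correlation_matrix(feats, ab))
  write_table(cm, file.path(out_dir, "correlation_matrix.csv"))
  tt <- stage("associate", feature_group_ttests(feats, ab))
  utils::write.csv(tt, file.path(out_dir, "group_ttests.csv"),
                   row.names = FALSE)
  log_line("associate: ", nrow(scan), " pair tests")

  evals <- list()
  for (pop in populations) {
    evals[[pop]] <- stage(paste0("classify:", pop), {
      y <- ab$labels[rownames(feats), pop]
      sel <- rfe_select(feats, y, candidate_sizes = rfe_sizes, seed = seed)
      cv <- loocv_eval(feats[, sel, drop = FALSE], y, hyper, seed = seed)
      model <- fit_classifier(feats[, sel, drop = FALSE], y, hyper, seed)
      ext <- external_eval(model, feats_test[, sel, drop = FALSE],
                           ab_test$labels[rownames(feats_test), pop])
      list(population = pop, selected = as.character(sel),
           n_selected = length(sel), loocv_auc = cv$auc,
           external_auc = ext$auc, selection_mode = "rfe_outside_loocv",
           seed = seed)
    })
  }
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(evals, file.path(out_dir, "model_evals.json"),
                         auto_unbox = TRUE, digits = NA)
  log_line("classify: ", length(evals), " population models")

  batch <- stage("batch_check", pca_batch_check(feats, feats_test))
  log_line("batch_check: silhouette ", signif(batch$silhouette, 3))

  invisible(list(features = feats, features_test = feats_test,
                 abundance = ab, abundance_test = ab_test, scan = scan,
                 cormat = cm, ttests = tt, evals = evals, batch = batch))
}
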