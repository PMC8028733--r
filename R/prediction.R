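#' Recursive feature elimination with random-forest importance
#'
#' Backward selection: within each cross-validation fold a random forest is
#' fit on the training part and its importance ranking defines, for every
#' candidate size k, the top-k feature subset whose held-out accuracy is
#' recorded. The size with the best mean CV accuracy wins (ties go to the
#' smaller size), and the returned set is the top-k features by importance
#' on the full data.
#'
#' @param X Samples x features numeric matrix.
#' @param y Binary labels (`"high"`/`"low"`, factor or character).
#' @param candidate_sizes Candidate subset sizes (default
#'   `c(2, 3, 4, 6, 8, 10, 12, 16, 20)`, clipped to `ncol(X)`).
#' @param folds,repeats Internal resampling: `folds`-fold CV repeated
#'   `repeats` times (defaults 5 and 5).
#' @param ntree Trees per forest (default 200).
#' @param seed Integer seed; the selection is deterministic given it.
#' @return Character vector of selected feature names, with attributes
#'   `size_accuracy` (mean CV accuracy per candidate size) and `best_size`.
#' @export
rfe_select <- function(X, y, candidate_sizes = c(2, 3, 4, 6, 8, 10, 12, 16, 20),
                       folds = 5L, repeats = 5L, ntree = 200L, seed = 1L) {
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) stop("`y` must have exactly 2 classes")
  n <- nrow(X)
  if (n < 10L) stop("need >= 10 samples for RFE")
  sizes <- sort(unique(pmin(candidate_sizes, ncol(X))))
  acc <- matrix(0, length(sizes), 0)
  withr::with_seed(seed, {
    accs <- matrix(NA_real_, length(sizes), folds * repeats)
    col <- 0L
    for (rep_i in seq_len(repeats)) {
      fold_id <- sample(rep_len(seq_len(folds), n))
      for (f in seq_len(folds)) {
        col <- col + 1L
        tr <- fold_id != f
        if (nlevels(droplevels(y[tr])) < 2L) next
        rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                         ntree = ntree, importance = TRUE)
        imp <- randomForest::importance(rf, type = 2)[, 1]
        ranking <- names(sort(imp, decreasing = TRUE))
        for (si in seq_along(sizes)) {
          top <- ranking[seq_len(sizes[si])]
          rf_k <- randomForest::randomForest(X[tr, top, drop = FALSE], y[tr],
                                             ntree = ntree)
          pred <- stats::predict(rf_k, X[!tr, top, drop = FALSE])
          accs[si, col] <- mean(pred == y[!tr])
        }
      }
    }
    size_acc <- rowMeans(accs, na.rm = TRUE)
    best <- sizes[which.max(size_acc)]        # which.max: first max = smallest
    rf_full <- randomForest::randomForest(X, y, ntree = ntree,
                                          importance = TRUE)
    imp_full <- randomForest::importance(rf_full, type = 2)[, 1]
    selected <- names(sort(imp_full, decreasing = TRUE))[seq_len(best)]
  })
  structure(selected,
            size_accuracy = stats::setNames(size_acc, sizes),
            best_size = best)
}

# canonical binary coding: "high" (or second factor level) -> 1
label01 <- function(y) {
  y <- as.character(y)
  u <- sort(unique(y))
  if (length(u) != 2L) stop("`y` must be binary, got: ",
                            paste(u, collapse = ", "))
  pos <- if ("high" %in% u) "high" else u[2]
  as.integer(y == pos)
}

#' Gradient-boosted binary classifier
#'
#' A binary logistic extreme-gradient-boosting model; returns a scoring
#' function mapping a feature matrix to `P(high)`.
#'
#' @param X Samples x features matrix.
#' @param y Binary labels (`"high"` is the positive class).
#' @param hyper List of xgboost settings: `nrounds`, `max_depth`, `eta`
#'   (defaults 100, 3, 0.1).
#' @param seed Integer seed (training is deterministic given it).
#' @return Function `newX -> numeric scores in [0, 1]`, with the fitted
#'   booster in attribute `model`.
#' @export
fit_classifier <- function(X, y, hyper = list(), seed = 1L) {
  hy <- utils::modifyList(list(nrounds = 100L, max_depth = 3L, eta = 0.1),
                          hyper)
  y01 <- label01(y)
  X <- as.matrix(X)
  withr::with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(X, label = y01, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hy$max_depth,
                    eta = hy$eta, nthread = 1, seed = seed),
      data = dtrain, nrounds = hy$nrounds, verbose = 0)
  })
  fn <- function(newX) {
    newX <- as.matrix(newX)[, colnames(X), drop = FALSE]
    stats::predict(booster, xgboost::xgb.DMatrix(newX, nthread = 1))
  }
  attr(fn, "model") <- booster
  fn
}

#' Leave-one-out cross-validation with pooled ROC
#'
#' For each sample the classifier is trained on the remaining n - 1 and
#' scores the held-out one; all held-out scores are pooled into a single
#' ROC/AUC. Folds whose training labels collapse to one class are flagged
#' and scored at the base rate.
#'
#' @inheritParams fit_classifier
#' @return List with `scores` (n held-out scores), `labels`, `auc`, `roc`
#'   (FPR/TPR data frame) and `flagged` (indices of single-class folds).
#' @export
loocv_eval <- function(X, y, hyper = list(), seed = 1L) {
  X <- as.matrix(X)
  y01 <- label01(y)
  n <- nrow(X)
  scores <- numeric(n)
  flagged <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y01[-i]
    if (length(unique(ytr)) < 2L) {
      flagged <- c(flagged, i)
      scores[i] <- mean(ytr)
      next
    }
    f <- fit_classifier(X[-i, , drop = FALSE], ytr, hyper,
                        seed = seed + i)
    scores[i] <- f(X[i, , drop = FALSE])
  }
  if (length(flagged))
    message(length(flagged), " LOOCV fold(s) had single-class training ",
            "labels; scored at the base rate")
  ra <- roc_auc(scores, y01)
  list(scores = scores, labels = y01, auc = ra$auc, roc = ra$roc,
       flagged = flagged)
}

#' External-cohort evaluation
#'
#' Applies a trained scoring function unchanged to an external test cohort
#' (whose labels come from its own median stratification).
#'
#' @param model Scoring function from [fit_classifier()].
#' @param X_test,y_test Test features and binary labels.
#' @return List with `auc`, `roc`, `scores`.
#' @export
external_eval <- function(model, X_test, y_test) {
  s <- model(X_test)
  ra <- roc_auc(s, label01(y_test))
  list(auc = ra$auc, roc = ra$roc, scores = s)
}

#' ROC curve and AUC
#'
#' Rank-based AUC with midrank tie handling and the trapezoidal ROC curve
#' (computed via pROC).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or `"low"`/`"high"`).
#' @return List with `auc` and `roc` (data frame of FPR, TPR from (0,0) to
#'   (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  y01 <- if (all(labels %in% c(0, 1))) as.integer(labels) else label01(labels)
  if (length(unique(y01)) < 2L) stop("need both classes for a ROC curve")
  r <- pROC::roc(response = y01, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  roc_df <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), ]
  rownames(roc_df) <- NULL
  list(auc = as.numeric(r$auc), roc = roc_df)
}

#' Permutation null for the pooled LOOCV AUC
#'
#' Re-runs the full LOOCV (training refit per fold) on label permutations
#' and collects the pooled AUCs; under the null the distribution is centred
#' at 0.5.
#'
#' @inheritParams loocv_eval
#' @param n_perm Number of permutations.
#' @return Numeric vector of `n_perm` AUCs.
#' @export
permutation_null_auc <- function(X, y, n_perm = 200L, hyper = list(),
                                 seed = 1L) {
  y01 <- label01(y)
  perms <- withr::with_seed(seed, replicate(n_perm, sample(y01),
                                            simplify = FALSE))
  vapply(seq_len(n_perm), function(k)
    loocv_eval(X, perms[[k]], hyper, seed = seed + 31L * k)$auc,
    numeric(1))
}

#' PCA batch-separation diagnostic
#'
#' Pools two feature tables, z-scores each feature, projects on the top two
#' principal components and reports the silhouette coefficient of the
#' cohort labels — near 0 when no batch structure exists, large and
#' positive under an institution batch effect.
#'
#' @param features_A,features_B Lesions x features matrices with identical
#'   feature columns.
#' @return List with `coords` (n x 2 PC scores), `batch` (label vector) and
#'   `silhouette` (mean silhouette width).
#' @export
pca_batch_check <- function(features_A, features_B) {
  stopifnot(identical(colnames(features_A), colnames(features_B)))
  X <- rbind(features_A, features_B)
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  Z <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  batch <- rep(c(1L, 2L), c(nrow(features_A), nrow(features_B)))
  sil <- cluster::silhouette(batch, stats::dist(coords))
  list(coords = coords, batch = batch,
       silhouette = mean(sil[, "sil_width"]))
}
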