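test_that("RFE returns the forced size and is seed-deterministic", {
  withr::with_seed(501, pc <- planted_classes(n = 40, n_inf = 3, n_noise = 7,
                                              d = 2))
  s1 <- rfe_select(pc$X, pc$y, candidate_sizes = 4, folds = 3, repeats = 2,
                   ntree = 50, seed = 9)
  expect_length(s1, 4)
  s2 <- rfe_select(pc$X, pc$y, candidate_sizes = 4, folds = 3, repeats = 2,
                   ntree = 50, seed = 9)
  expect_identical(as.character(s1), as.character(s2))
  expect_error(rfe_select(pc$X, rep("high", 40)), "2 classes")
})

test_that("RFE recovers planted informative features", {
  withr::with_seed(502, pc <- planted_classes(n = 200, n_inf = 5,
                                              n_noise = 95, d = 1.5))
  sel <- rfe_select(pc$X, pc$y, candidate_sizes = c(2, 4, 6, 8, 12),
                    folds = 5, repeats = 2, ntree = 100, seed = 7)
  hits <- sum(startsWith(as.character(sel), "inf_"))
  expect_gte(hits, 4)
})

test_that("boosted classifier separates separable data and is reproducible", {
  withr::with_seed(503, {
    X <- cbind(a = c(runif(40, 0.2, 2), runif(40, -2, -0.2)),
               b = rnorm(80))
    rownames(X) <- paste0("s", 1:80)
    y <- ifelse(X[, "a"] > 0, "high", "low")  # separable with a margin
  })
  f <- fit_classifier(X, y, seed = 3)
  expect_equal(roc_auc(f(X), y)$auc, 1.0)
  f2 <- fit_classifier(X, y, seed = 3)
  expect_equal(f(X), f2(X))
  # constant features -> scores collapse to the base rate
  Xc <- matrix(1, 40, 2, dimnames = list(paste0("s", 1:40), c("a", "b")))
  yc <- rep(c("high", "low"), each = 20)
  fc <- fit_classifier(Xc, yc, seed = 3)
  expect_lt(diff(range(fc(Xc))), 1e-6)
  expect_equal(mean(fc(Xc)), 0.5, tolerance = 0.1)
  expect_error(fit_classifier(X, rep("a", 80)), "binary")
})

test_that("ROC/AUC matches the Mann-Whitney pair-count identity", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  withr::with_seed(504, {
    for (rep in 1:25) {
      n <- sample(6:30, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("ROC curve runs from (0,0) to (1,1) monotonically", {
  withr::with_seed(505, r <- roc_auc(runif(30), rbinom(30, 1, 0.5)))
  expect_equal(unlist(r$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(506, {
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
  })
  a1 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a1)
  expect_equal(roc_auc(2 * s - 7, y)$auc, a1)
})

test_that("LOOCV scores every sample and detects planted separation", {
  withr::with_seed(507, pc <- planted_classes(n = 30, n_inf = 3, n_noise = 3,
                                              d = 2.5))
  cv <- loocv_eval(pc$X, pc$y, hyper = list(nrounds = 40), seed = 5)
  expect_length(cv$scores, 30)
  expect_gt(cv$auc, 0.8)
  cv2 <- loocv_eval(pc$X, pc$y, hyper = list(nrounds = 40), seed = 5)
  expect_equal(cv$auc, cv2$auc)             # fixed-seed reproducibility
})

test_that("external evaluation flips with label inversion", {
  withr::with_seed(508, {
    pc <- planted_classes(n = 40, d = 2)
    pt <- planted_classes(n = 40, d = 2)
  })
  f <- fit_classifier(pc$X, pc$y, seed = 11)
  e1 <- external_eval(f, pt$X, pt$y)
  inv <- ifelse(pt$y == "high", "low", "high")
  e2 <- external_eval(f, pt$X, inv)
  expect_equal(e2$auc, 1 - e1$auc, tolerance = 1e-12)
})

test_that("PCA batch check is near zero without and large with a shift", {
  withr::with_seed(509, {
    fa <- matrix(rnorm(25 * 12), 25, 12,
                 dimnames = list(paste0("a", 1:25), paste0("f", 1:12)))
    fb <- matrix(rnorm(25 * 12), 25, 12,
                 dimnames = list(paste0("b", 1:25), paste0("f", 1:12)))
  })
  same <- pca_batch_check(fa, fb)
  expect_lt(abs(same$silhouette), 0.1)
  fb_shift <- fb
  fb_shift[, 1:6] <- fb_shift[, 1:6] + 5    # 5 pooled-SD shift on half
  shifted <- pca_batch_check(fa, fb_shift)
  expect_gt(shifted$silhouette, 0.5)
  # deterministic up to per-component sign
  again <- pca_batch_check(fa, fb_shift)
  expect_equal(abs(again$coords), abs(shifted$coords))
})
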