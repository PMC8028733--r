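mk_abundance <- function(A) {
  structure(list(scores = A, labels = NULL, thresholds = NULL),
            class = "abundance_table")
}

test_that("perfect linearity gives r = 1, slope 2, tiny p", {
  x <- 1:10
  X <- matrix(x, 10, 1, dimnames = list(paste0("s", 1:10), "f1"))
  A <- matrix(2 * x, 10, 10,
              dimnames = list(paste0("s", 1:10), cell_populations()))
  res <- univariate_scan(X, mk_abundance(A))
  expect_equal(res$r, rep(1, 10), tolerance = 1e-12)
  expect_equal(res$slope, rep(2, 10), tolerance = 1e-12)
  expect_true(all(res$p < 1e-10))
  expect_true(all(res$p_adj >= res$p))
})

test_that("scan p equals the Pearson correlation test p", {
  withr::with_seed(401, {
    X <- matrix(rnorm(20 * 5), 20, 5,
                dimnames = list(paste0("s", 1:20), paste0("f", 1:5)))
    A <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(paste0("s", 1:20), cell_populations()))
  })
  res <- univariate_scan(X, mk_abundance(A))
  for (k in sample(nrow(res), 10)) {
    ct <- cor.test(X[, res$feature[k]], A[, res$population[k]])
    expect_equal(res$p[k], ct$p.value, tolerance = 1e-9)
    expect_equal(res$r[k], unname(ct$estimate), tolerance = 1e-9)
  }
})

test_that("null features produce approximately uniform p-values", {
  withr::with_seed(402, {
    X <- matrix(rnorm(100 * 1000), 100, 1000,
                dimnames = list(sprintf("s%03d", 1:100), paste0("f", 1:1000)))
    A <- matrix(rnorm(100 * 10), 100, 10,
                dimnames = list(sprintf("s%03d", 1:100), cell_populations()))
  })
  res <- univariate_scan(X, mk_abundance(A))
  p1 <- res$p[res$population == "fibroblasts"]
  ks <- suppressWarnings(ks.test(p1, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("zero-variance features are annotated, not silently dropped", {
  withr::with_seed(403, {
    X <- cbind(flat = rep(1, 12), ok = rnorm(12))
    rownames(X) <- paste0("s", 1:12)
    A <- matrix(rnorm(12 * 10), 12, 10,
                dimnames = list(paste0("s", 1:12), cell_populations()))
  })
  expect_warning(res <- univariate_scan(X, mk_abundance(A)), "zero-variance")
  expect_equal(nrow(res), 20)               # all pairs present
  expect_true(all(is.na(res$p[res$note == "zero_variance"])))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(404, {
    for (rep in 1:50) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q <= 1) && all(q >= p))
    }
  })
})

test_that("correlation matrix is consistent with the scan and ordered", {
  withr::with_seed(405, {
    X <- matrix(rnorm(15 * 8), 15, 8,
                dimnames = list(paste0("s", 1:15),
                                c("shape_voxel_volume", "fo_mean",
                                  "kin_agg_pe_mean", "glcm_contrast",
                                  "f5", "f6", "f7", "f8")))
    A <- matrix(rnorm(15 * 10), 15, 10,
                dimnames = list(paste0("s", 1:15), cell_populations()))
  })
  ab <- mk_abundance(A)
  cm <- correlation_matrix(X, ab)
  scan <- univariate_scan(X, ab)
  for (k in sample(nrow(scan), 10))
    expect_equal(cm[scan$feature[k], scan$population[k]], scan$r[k])
  expect_true(all(abs(cm) <= 1))
  fam <- attr(cm, "family")
  expect_equal(fam[1], "shape")             # grouped rows: shape first
})

test_that("sample order permutation leaves the scan unchanged", {
  withr::with_seed(406, {
    X <- matrix(rnorm(12 * 4), 12, 4,
                dimnames = list(paste0("s", 1:12), paste0("f", 1:4)))
    A <- matrix(rnorm(12 * 10), 12, 10,
                dimnames = list(paste0("s", 1:12), cell_populations()))
    perm <- sample(12)
  })
  r1 <- univariate_scan(X, mk_abundance(A))
  r2 <- univariate_scan(X[perm, ], mk_abundance(A[perm, ]))
  expect_equal(r1, r2)
})

test_that("Welch t-test matches the closed form and its degeneracies", {
  same <- group_ttest(c(1, 2, 3, 1, 2, 3),
                      c("high", "high", "high", "low", "low", "low"))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  tt <- group_ttest(c(4, 5, 6, 1, 2, 3),
                    c("high", "high", "high", "low", "low", "low"))
  expect_equal(abs(tt$t), 3.674, tolerance = 1e-3)
  expect_equal(tt$p, 0.0213, tolerance = 1e-2)
  expect_error(group_ttest(1:4, rep("high", 4)), "single-class")
})

test_that("planted mean-PE coupling is detected by the group t-tests", {
  # cohort-level contrast: mean PE separates high/low for the planted
  # population while an unplanted feature does not systematically
  withr::with_seed(407, {
    n <- 200
    u <- rnorm(n)
    meanpe <- 1 + 0.25 * u + rnorm(n, 0, 0.05)
    vol <- rnorm(n, 50, 10)                  # unplanted
    endo <- 3 + 0.8 * u + sqrt(1 - 0.64) * rnorm(n)
    A <- matrix(rnorm(n * 10, 3), n, 10,
                dimnames = list(sprintf("s%03d", 1:n), cell_populations()))
    A[, "endothelial_cells"] <- endo
  })
  X <- cbind(shape_voxel_volume = vol, kin_agg_pe_mean = meanpe)
  rownames(X) <- rownames(A)
  ab <- stratify_median(mk_abundance(A))
  res <- feature_group_ttests(X, ab)
  p_pe <- res$p_adj[res$feature == "kin_agg_pe_mean" &
                      res$population == "endothelial_cells"]
  p_vol <- res$p_adj[res$feature == "shape_voxel_volume" &
                       res$population == "endothelial_cells"]
  expect_lt(p_pe, 0.05)
  expect_gt(p_vol, 0.05)
})
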