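test_that("rescale-quantize respects the bin-width level cap", {
  withr::with_seed(201, {
    vol <- array(runif(4^3, 0, 1000), c(4, 4, 4))
    mask <- array(1L, c(4, 4, 4))
  })
  roi <- rescale_quantize(vol, mask, bits = 8, bin_width = 25)
  expect_lte(roi$n_levels, ceiling(256 / 25))
  # brute-force per-voxel recomputation
  v <- vol[mask == 1]
  resc <- (v - min(v)) / (max(v) - min(v)) * 255
  expect_equal(roi$levels[mask == 1], as.integer(floor(resc / 25)) + 1L)
  # constant ROI
  roi_c <- rescale_quantize(array(7, c(2, 2, 2)), array(1L, c(2, 2, 2)))
  expect_equal(roi_c$n_levels, 1L)
})

test_that("shape features match analytic solids", {
  # single 1 mm^3 voxel
  m1 <- array(0L, c(3, 3, 3)); m1[2, 2, 2] <- 1L
  s1 <- shape_features(m1, c(1, 1, 1))
  expect_equal(unname(s1["shape_voxel_volume"]), 1)
  expect_equal(unname(s1[c("shape_major_axis_length", "shape_elongation")]),
               c(0, 0))
  # digital ball, radius 10, isotropic 1 mm
  d <- c(23, 23, 23)
  co <- arrayInd(seq_len(prod(d)), d)
  ball <- array(as.integer(rowSums(sweep(co, 2, c(12, 12, 12))^2) <= 100), d)
  sb <- shape_features(ball, c(1, 1, 1))
  expect_gte(unname(sb["shape_sphericity"]), 0.95)
  expect_lte(unname(sb["shape_sphericity"]), 1.0)
  expect_equal(unname(sb["shape_max_3d_diameter"]), 20, tolerance = 0.05)
  # prolate ellipsoid semi-axes (10, 4, 4) mm
  d2 <- c(25, 11, 11)
  co2 <- arrayInd(seq_len(prod(d2)), d2)
  ell <- array(as.integer(((co2[, 1] - 13) / 10)^2 + ((co2[, 2] - 6) / 4)^2 +
                            ((co2[, 3] - 6) / 4)^2 <= 1), d2)
  se <- shape_features(ell, c(1, 1, 1))
  expect_equal(unname(se["shape_elongation"]), 0.4, tolerance = 0.05)
  expect_equal(unname(se["shape_flatness"]), 0.4, tolerance = 0.05)
})

test_that("first-order features match direct formulas", {
  withr::with_seed(202, {
    dims <- c(5, 5, 5)
    phases <- lapply(1:4, function(k) array(runif(prod(dims), 50, 300), dims))
    mask <- array(rbinom(prod(dims), 1, 0.7), dims); mask[1] <- 1L
  })
  st <- dce_study(phases, mask, c(1, 2, 2), c(0, 1, 2, 3))
  fo <- first_order_features(st)
  expect_length(fo, 22)
  x <- phases[[2]][mask == 1]
  o <- oracle_first_order(x)
  for (nm in names(o))
    expect_equal(unname(fo[paste0("fo_", nm)]), unname(o[nm]),
                 tolerance = 1e-12, label = nm)
  expect_equal(unname(fo["fo_total_energy"]), 4 * sum(x^2), tolerance = 1e-9)
  expect_equal(unname(fo["fo_mean_pre"]), mean(phases[[1]][mask == 1]))
  # constant ROI degenerates cleanly
  stc <- uniform_study(c(0.5, 0.5, 0.5))
  foc <- first_order_features(stc)
  expect_equal(unname(foc[c("fo_variance", "fo_entropy", "fo_uniformity",
                            "fo_skewness")]), c(0, 0, 1, 0))
  # symmetric two-point ROI has zero skewness
  m2 <- array(0L, c(2, 2, 2)); m2[1, 1, 1] <- 1L; m2[2, 1, 1] <- 1L
  ph <- lapply(1:4, function(k) array(c(10, 30), c(2, 2, 2)))
  st2 <- dce_study(ph, m2, c(1, 1, 1), c(0, 1, 2, 3))
  expect_equal(unname(first_order_features(st2)["fo_skewness"]), 0)
})

test_that("constant ROI degenerates every texture family without NaN", {
  roi <- rescale_quantize(array(5, c(3, 3, 3)), array(1L, c(3, 3, 3)))
  glcm <- texture_matrix_features(roi, "GLCM")
  expect_equal(unname(glcm[c("glcm_joint_energy", "glcm_contrast")]), c(1, 0))
  glszm <- texture_matrix_features(roi, "GLSZM")
  expect_equal(unname(glszm["glszm_zp"]), 1 / 27)   # one zone of size n
  for (fam in c("GLCM", "GLRLM", "GLSZM", "GLDM", "NGTDM"))
    expect_true(all(is.finite(texture_matrix_features(roi, fam))),
                label = fam)
})

test_that("static vector is complete, deterministic, intensity-aware", {
  cfg <- cohort_config(n_lesions = 2, seed = 41)
  l <- gen_lesion_study(cfg, 1)
  v <- static_feature_vector(l$study)
  expect_identical(names(v), static_feature_catalog())
  expect_length(v, 111)
  expect_true(all(is.finite(v)))
  expect_identical(v, static_feature_vector(l$study))
  # shape block depends only on the mask
  st2 <- l$study
  for (k in 1:4) st2$phases[[k]] <- st2$phases[[k]] * 3 + 11
  v2 <- static_feature_vector(st2)
  shp <- startsWith(names(v), "shape_")
  expect_equal(v[shp], v2[shp])
})

test_that("90-degree rotation leaves direction-averaged families unchanged", {
  withr::with_seed(203, {
    dims <- c(5, 5, 5)
    vol <- array(runif(prod(dims), 0, 100), dims)
    mask <- array(rbinom(prod(dims), 1, 0.8), dims); mask[1] <- 1L
  })
  rot <- function(a) aperm(a[, , dim(a)[3]:1, drop = FALSE], c(3, 2, 1))
  roi1 <- rescale_quantize(vol, mask)
  roi2 <- rescale_quantize(rot(vol), rot(mask))
  for (fam in c("GLCM", "GLRLM"))
    expect_equal(texture_matrix_features(roi1, fam),
                 texture_matrix_features(roi2, fam), tolerance = 1e-10,
                 label = fam)
})
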