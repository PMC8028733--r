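test_that("voxel kinetics match hand-computed curves", {
  k <- voxel_kinetics(c(100, 200, 180, 160), c(0, 1, 2, 3))
  expect_equal(k, list(PE = 1, TTP = 1, WIS = 1, WOS = -0.2))
  flat <- voxel_kinetics(c(100, 100, 100, 100), c(0, 1, 2, 3))
  expect_equal(flat, list(PE = 0, TTP = 1, WIS = 0, WOS = 0))
  late <- voxel_kinetics(c(100, 120, 140, 200), c(0, 1, 2, 3))
  expect_equal(late, list(PE = 1, TTP = 3, WIS = 1 / 3, WOS = 0))
})

test_that("parameter maps agree with the per-voxel computation", {
  withr::with_seed(1, {
    dims <- c(5, 5, 5)
    phases <- lapply(1:4, function(k) array(runif(prod(dims), 80, 250), dims))
    mask <- array(rbinom(prod(dims), 1, 0.6), dims)
    mask[1] <- 1L
  })
  st <- dce_study(phases, mask, c(1, 1, 1), c(0, 1, 2, 3))
  maps <- kinetic_param_maps(st)
  for (idx in which(st$mask == 1)[1:20]) {
    p <- arrayInd(idx, dims)
    sig <- vapply(st$phases, function(ph) ph[p], numeric(1))
    k <- voxel_kinetics(sig, st$times)
    expect_equal(maps$PE[idx], k$PE)
    expect_equal(maps$TTP[idx], k$TTP)
    expect_equal(maps$WIS[idx], k$WIS)
    expect_equal(maps$WOS[idx], k$WOS)
  }
})

test_that("aggregate features on homogeneous and two-voxel lesions", {
  st <- uniform_study(c(1, 0.8, 0.6))
  ag <- aggregate_features(st)
  expect_equal(unname(ag[c("kin_agg_pe_mean", "kin_agg_pe_sd",
                           "kin_agg_mpe", "kin_agg_hotspot")]),
               c(1, 0, 1, 1))
  # two isolated voxels with PE 0.5 and 1.5
  pe <- array(NA_real_, c(5, 5, 5))
  mask <- array(0L, c(5, 5, 5))
  mask[1, 1, 1] <- 1L; mask[5, 5, 5] <- 1L
  pe[1, 1, 1] <- 0.5; pe[5, 5, 5] <- 1.5
  st2 <- pe_map_study(pe, mask)
  ag2 <- aggregate_features(st2)
  expect_equal(unname(ag2[c("kin_agg_pe_mean", "kin_agg_mpe",
                            "kin_agg_hotspot")]), c(1, 1.5, 1.5))
})

test_that("hot spot equals the exhaustive neighbourhood oracle", {
  withr::with_seed(42, {
    dims <- c(8, 8, 8)
    mask <- array(rbinom(prod(dims), 1, 0.7), dims)
    mask[1] <- 1L
    pe <- array(runif(prod(dims)), dims)
  })
  pe[mask == 0] <- NA
  st <- pe_map_study(pe, mask)
  maps <- kinetic_param_maps(st)
  expect_equal(radtme:::hotspot_pe(maps$PE, mask),
               oracle_hotspot(maps$PE, mask), tolerance = 1e-12)
})

test_that("TTP partition counts proportions and recovers ground truth", {
  # 10 voxels peaking at phases (1 x5, 2 x3, 3 x2) -> (0.5, 0.3, 0.2)
  dims <- c(1, 2, 5)
  mask <- array(1L, dims)
  peaks <- c(rep(1, 5), rep(2, 3), rep(3, 2))
  phases <- list(array(100, dims), array(100, dims), array(100, dims),
                 array(100, dims))
  for (v in seq_len(10)) phases[[peaks[v] + 1]][v] <- 200
  st <- dce_study(phases, mask, c(1, 1, 1), c(0, 1, 2, 3))
  tp <- ttp_partition(st)
  expect_equal(unname(tp$proportions), c(0.5, 0.3, 0.2))
  expect_equal(sum(tp$proportions), 1, tolerance = 1e-12)

  cfg <- cohort_config(n_lesions = 2, noise_sd = 0, seed = 9)
  l <- gen_lesion_study(cfg, 1)
  tp2 <- ttp_partition(l$study)
  inm <- l$study$mask == 1
  expect_identical(tp2$labels[inm], l$truth$archetype[inm])
})

test_that("heterogeneity features use the emptiness convention and analytics", {
  st <- uniform_study(c(1, 0.8, 0.6))       # single archetype: quick
  h <- heterogeneity_features(st)
  expect_length(h, 21)
  empty <- grepl("intermediate|slow", names(h))
  expect_equal(sum(empty), 14)
  expect_true(all(h[empty] == 0))
  expect_equal(unname(h["kin_het_quick_prop"]), 1)

  cfg <- cohort_config(n_lesions = 2, noise_sd = 0,
                       ttp_fractions = c(0.5, 0.5, 0), seed = 13)
  l <- gen_lesion_study(cfg, 1)
  h2 <- heterogeneity_features(l$study)
  ap <- cfg$archetype_params
  amp <- l$truth$amp
  # analytic per-archetype kinetics of the piecewise-linear curves
  expect_equal(unname(h2["kin_het_quick_wis_mean"]),
               ap$quick$peak_level * amp / 1, tolerance = 1e-9)
  expect_equal(unname(h2["kin_het_intermediate_wis_mean"]),
               ap$intermediate$peak_level * amp / 2, tolerance = 1e-9)
  expect_equal(unname(h2["kin_het_quick_wos_mean"]), -ap$quick$washout,
               tolerance = 1e-9)
  expect_equal(unname(h2["kin_het_quick_pe_sd"]), 0)
  expect_equal(sum(h2[grepl("_prop", names(h2))]), 1, tolerance = 1e-12)
})

test_that("kinetic vector has the full finite catalog and is deterministic", {
  cfg <- cohort_config(n_lesions = 2, seed = 17)
  l <- gen_lesion_study(cfg, 1)
  v1 <- kinetic_feature_vector(l$study)
  expect_identical(names(v1), kinetic_feature_catalog())
  expect_length(v1, 88)
  expect_true(all(is.finite(v1)))
  expect_identical(v1, kinetic_feature_vector(l$study))
  expect_false(anyDuplicated(names(v1)) > 0)
})

test_that("scaling post-contrast intensities scales PE/WIS/|WOS| linearly", {
  cfg <- cohort_config(n_lesions = 2, noise_sd = 0, seed = 21)
  l <- gen_lesion_study(cfg, 1)
  st <- l$study
  k <- 1.7
  st2 <- st
  base <- st$phases[[1]]
  for (i in 2:4) st2$phases[[i]] <- base + k * (st$phases[[i]] - base)
  m1 <- kinetic_param_maps(st); m2 <- kinetic_param_maps(st2)
  inm <- st$mask == 1
  expect_equal(m2$PE[inm], k * m1$PE[inm], tolerance = 1e-12)
  expect_equal(m2$WIS[inm], k * m1$WIS[inm], tolerance = 1e-12)
  expect_equal(m2$WOS[inm], k * m1$WOS[inm], tolerance = 1e-12)
  expect_equal(m2$TTP[inm], m1$TTP[inm])
  expect_equal(ttp_partition(st2)$proportions, ttp_partition(st)$proportions)
})
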