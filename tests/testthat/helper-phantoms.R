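# Phantom builders shared across the suite.

# random quantized ROI: ellipsoid-ish random mask inside dims, levels 1..L
rand_roi <- function(dims, L, p_mask = 0.7) {
  lev <- array(NA_integer_, dims)
  inmask <- array(stats::runif(prod(dims)) < p_mask, dims)
  if (!any(inmask)) inmask[1] <- TRUE
  lev[inmask] <- sample.int(L, sum(inmask), replace = TRUE)
  lev
}

# study whose every in-mask voxel has the same enhancement curve
uniform_study <- function(E, dims = c(4, 4, 4), baseline = 100,
                          times = c(0, 1, 2, 3), mask = NULL) {
  if (is.null(mask)) mask <- array(1L, dims)
  phases <- lapply(c(0, E), function(e) array(baseline * (1 + e), dims))
  dce_study(phases, mask, c(1, 1, 1), times)
}

# study built from a per-voxel PE map: each voxel peaks at phase 1 with its
# own PE and no washout
pe_map_study <- function(pe_map, mask, baseline = 100) {
  dims <- dim(pe_map)
  pe_map[is.na(pe_map)] <- 0
  phases <- list(array(baseline, dims),
                 baseline * (1 + pe_map),
                 baseline * (1 + pe_map),
                 baseline * (1 + pe_map))
  dce_study(phases, mask, c(1, 1, 1), c(0, 1, 2, 3))
}

# two-class feature matrix with planted standardized effect d on the first
# `n_inf` columns
planted_classes <- function(n = 60, n_inf = 5, n_noise = 15, d = 2) {
  y <- rep(c("low", "high"), length.out = n)
  X <- matrix(stats::rnorm(n * (n_inf + n_noise)), n,
              dimnames = list(sprintf("s%03d", 1:n),
                              c(sprintf("inf_%d", seq_len(n_inf)),
                                sprintf("noise_%d", seq_len(n_noise)))))
  X[, seq_len(n_inf)] <- X[, seq_len(n_inf)] + d * (y == "high")
  list(X = X, y = y)
}
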