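#' First-order intensity features
#'
#' Eighteen intensity statistics of the reference phase (first
#' post-contrast) over the mask — mean, median, min, max, range, 10th/90th
#' percentiles, IQR, variance, mean absolute deviation, robust MAD (within
#' the 10–90 percentile band), RMS, energy, total energy (energy times voxel
#' volume), entropy and uniformity (on the quantized levels), skewness and
#' kurtosis — plus the tumor mean intensity of each of the four phases,
#' 22 values in all.
#'
#' @param study A [dce_study()].
#' @param roi A [rescale_quantize()] of the reference phase (used for the
#'   entropy and uniformity bins).
#' @return Named numeric vector of 22 values (`fo_*`).
#' @export
first_order_features <- function(study,
                                 roi = rescale_quantize(study$phases[[2]],
                                                        study$mask)) {
  inmask <- study$mask == 1L
  x <- study$phases[[2]][inmask]
  qs <- unname(stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), type = 7))
  band <- x[x >= qs[1] & x <= qs[4]]
  ctr <- x - mean(x)
  s2 <- mean(ctr^2)
  lev <- roi$levels[inmask]
  p <- tabulate(lev, nbins = roi$n_levels) / length(lev)
  p <- p[p > 0]
  vv <- prod(study$spacing)
  c(fo_mean = mean(x),
    fo_median = stats::median(x),
    fo_min = min(x),
    fo_max = max(x),
    fo_range = diff(range(x)),
    fo_p10 = qs[1],
    fo_p90 = qs[4],
    fo_iqr = qs[3] - qs[2],
    fo_variance = s2,
    fo_mad = mean(abs(ctr)),
    fo_rmad = mean(abs(band - mean(band))),
    fo_rms = sqrt(mean(x^2)),
    fo_energy = sum(x^2),
    fo_total_energy = vv * sum(x^2),
    fo_entropy = -sum(p * log2(p)),
    fo_uniformity = sum(p^2),
    fo_skewness = if (s2 > 0) mean(ctr^3) / s2^1.5 else 0,
    fo_kurtosis = if (s2 > 0) mean(ctr^4) / s2^2 else 0,
    fo_mean_pre = mean(study$phases[[1]][inmask]),
    fo_mean_post1 = mean(study$phases[[2]][inmask]),
    fo_mean_post2 = mean(study$phases[[3]][inmask]),
    fo_mean_post3 = mean(study$phases[[4]][inmask]))
}

#' Texture-matrix feature families
#'
#' Computes one of the five gray-level matrix families on a quantized ROI:
#' GLCM (24 descriptors; 13 distance-1 offsets, symmetric, matrix-averaged),
#' GLRLM (16; 13 directions, feature-averaged), GLSZM (16; 26-connected
#' zones), GLDM (14; 26-neighbourhood dependence, alpha = 0) and NGTDM (5).
#' Degenerate single-level ROIs take closed-form values, never NaN.
#'
#' @param roi A [rescale_quantize()] (or any list with `levels`, `n_levels`).
#' @param family One of `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"GLDM"`, `"NGTDM"`.
#' @return Named numeric vector (24/16/16/14/5 values).
#' @export
texture_matrix_features <- function(roi,
                                    family = c("GLCM", "GLRLM", "GLSZM",
                                               "GLDM", "NGTDM")) {
  family <- match.arg(family)
  lev <- roi$levels
  L <- roi$n_levels
  switch(family,
         GLCM = glcm_features(glcm_matrix(lev, L)),
         GLRLM = {
           mats <- glrlm_matrices(lev, L)
           per <- vapply(mats, glrlm_features_one, numeric(16))
           out <- rowMeans(per)
           names(out) <- paste0("glrlm_", rownames(per))
           out
         },
         GLSZM = glszm_features(glszm_matrix(lev, L)),
         GLDM = gldm_features(gldm_matrix(lev, L)),
         NGTDM = ngtdm_features(ngtdm_matrix(lev, L)))
}

glcm_features <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mux <- sum(seq_len(L) * px)
  sx2 <- sum((seq_len(L) - mux)^2 * px)
  log2p <- function(x) ifelse(x > 0, log2(x), 0)
  pxy_dif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  da <- sum((0:(L - 1)) * pxy_dif)
  pxy_sum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))
  sa <- sum((2:(2 * L)) * pxy_sum)
  hx <- -sum(px * log2p(px))
  hxy <- -sum(P * log2p(P))
  pxpy <- outer(px, px)
  hxy1 <- -sum(P * log2p(pxpy))
  hxy2 <- -sum(pxpy * log2p(pxpy))
  offdiag <- abs(i - j) > 0
  inv_var <- sum(P[offdiag] / (i - j)[offdiag]^2)
  # MCC via the second-largest eigenvalue of Q(i,j) = sum_k p(i,k)p(j,k)/(px_i px_k)
  mcc <- if (L == 1L) 1 else {
    pos <- px > 0
    Pp <- P[pos, pos, drop = FALSE]
    pxp <- px[pos]
    Q <- matrix(0, sum(pos), sum(pos))
    for (k in seq_len(sum(pos)))
      Q <- Q + outer(Pp[, k], Pp[, k]) / (pxp * pxp[k])
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) < 2L) 1 else sqrt(max(ev[2], 0))
  }
  c(glcm_autocorrelation = sum(i * j * P),
    glcm_joint_average = mux,
    glcm_cluster_prominence = sum((i + j - 2 * mux)^4 * P),
    glcm_cluster_shade = sum((i + j - 2 * mux)^3 * P),
    glcm_cluster_tendency = sum((i + j - 2 * mux)^2 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = if (sx2 > 0) (sum(i * j * P) - mux^2) / sx2 else 0,
    glcm_difference_average = da,
    glcm_difference_entropy = -sum(pxy_dif * log2p(pxy_dif)),
    glcm_difference_variance = sum(((0:(L - 1)) - da)^2 * pxy_dif),
    glcm_id = sum(P / (1 + abs(i - j))),
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idmn = sum(P / (1 + (i - j)^2 / L^2)),
    glcm_idn = sum(P / (1 + abs(i - j) / L)),
    glcm_imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    glcm_imc2 = sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)),
    glcm_inverse_variance = inv_var,
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = hxy,
    glcm_max_probability = max(P),
    glcm_mcc = mcc,
    glcm_sum_average = sa,
    glcm_sum_entropy = -sum(pxy_sum * log2p(pxy_sum)),
    glcm_sum_squares = sum((i - mux)^2 * P))
}

glrlm_features_one <- function(R) {
  Nr <- sum(R)
  if (Nr == 0) R <- matrix(1, 1, 1)  # cannot happen for nonempty masks
  Nr <- sum(R)
  i <- row(R); l <- col(R)
  Np <- sum(R * l)
  ri <- rowSums(R); rl <- colSums(R)
  il <- seq_len(nrow(R)); ll <- seq_len(ncol(R))
  mu_i <- sum(il * ri) / Nr
  mu_l <- sum(ll * rl) / Nr
  p <- R / Nr
  c(sre = sum(rl / ll^2) / Nr,
    lre = sum(rl * ll^2) / Nr,
    gln = sum(ri^2) / Nr,
    glnn = sum(ri^2) / Nr^2,
    rln = sum(rl^2) / Nr,
    rlnn = sum(rl^2) / Nr^2,
    rp = Nr / Np,
    glv = sum((i - mu_i)^2 * p),
    rv = sum((l - mu_l)^2 * p),
    re = -sum(ifelse(p > 0, p * log2(p), 0)),
    lglre = sum(ri / il^2) / Nr,
    hglre = sum(ri * il^2) / Nr,
    srlgle = sum(R / (i^2 * l^2)) / Nr,
    srhgle = sum(R * i^2 / l^2) / Nr,
    lrlgle = sum(R * l^2 / i^2) / Nr,
    lrhgle = sum(R * i^2 * l^2) / Nr)
}

glszm_features <- function(Z) {
  Nz <- sum(Z)
  Np <- sum(Z * col(Z))
  i <- row(Z); s <- col(Z)
  zi <- rowSums(Z); zs <- colSums(Z)
  il <- seq_len(nrow(Z)); sl <- seq_len(ncol(Z))
  p <- Z / Nz
  mu_i <- sum(il * zi) / Nz
  mu_s <- sum(sl * zs) / Nz
  c(glszm_sae = sum(zs / sl^2) / Nz,
    glszm_lae = sum(zs * sl^2) / Nz,
    glszm_gln = sum(zi^2) / Nz,
    glszm_glnn = sum(zi^2) / Nz^2,
    glszm_szn = sum(zs^2) / Nz,
    glszm_sznn = sum(zs^2) / Nz^2,
    glszm_zp = Nz / Np,
    glszm_glv = sum((i - mu_i)^2 * p),
    glszm_zv = sum((s - mu_s)^2 * p),
    glszm_ze = -sum(ifelse(p > 0, p * log2(p), 0)),
    glszm_lglze = sum(zi / il^2) / Nz,
    glszm_hglze = sum(zi * il^2) / Nz,
    glszm_salgle = sum(Z / (i^2 * s^2)) / Nz,
    glszm_sahgle = sum(Z * i^2 / s^2) / Nz,
    glszm_lalgle = sum(Z * s^2 / i^2) / Nz,
    glszm_lahgle = sum(Z * i^2 * s^2) / Nz)
}

gldm_features <- function(D) {
  Nz <- sum(D)
  i <- row(D); j <- col(D)
  di <- rowSums(D); dj <- colSums(D)
  il <- seq_len(nrow(D)); jl <- seq_len(ncol(D))
  p <- D / Nz
  mu_i <- sum(il * di) / Nz
  mu_j <- sum(jl * dj) / Nz
  c(gldm_sde = sum(dj / jl^2) / Nz,
    gldm_lde = sum(dj * jl^2) / Nz,
    gldm_gln = sum(di^2) / Nz,
    gldm_dn = sum(dj^2) / Nz,
    gldm_dnn = sum(dj^2) / Nz^2,
    gldm_glv = sum((i - mu_i)^2 * p),
    gldm_dv = sum((j - mu_j)^2 * p),
    gldm_de = -sum(ifelse(p > 0, p * log2(p), 0)),
    gldm_lgle = sum(di / il^2) / Nz,
    gldm_hgle = sum(di * il^2) / Nz,
    gldm_sdlgle = sum(D / (i^2 * j^2)) / Nz,
    gldm_sdhgle = sum(D * i^2 / j^2) / Nz,
    gldm_ldlgle = sum(D * j^2 / i^2) / Nz,
    gldm_ldhgle = sum(D * i^2 * j^2) / Nz)
}

ngtdm_features <- function(ng) {
  n <- ng$n; s <- ng$s
  Nv <- ng$n_valid
  if (Nv == 0) return(c(ngtdm_coarseness = 1e6, ngtdm_contrast = 0,
                        ngtdm_busyness = 0, ngtdm_complexity = 0,
                        ngtdm_strength = 0))
  p <- n / Nv
  act <- p > 0
  ii <- which(act)
  Ngp <- length(ii)
  denom_coar <- sum(p * s)
  coars <- if (denom_coar > 0) 1 / denom_coar else 1e6
  contrast <- if (Ngp > 1) {
    sum(outer(p[ii], p[ii]) * outer(ii, ii, `-`)^2) /
      (Ngp * (Ngp - 1)) * sum(s) / Nv
  } else 0
  busy_den <- sum(abs(outer(ii * p[ii], ii * p[ii], `-`)))
  busyness <- if (busy_den > 0) denom_coar / busy_den else 0
  complexity <- if (Ngp > 1) {
    sum(abs(outer(ii, ii, `-`)) *
          (outer(p[ii] * s[ii], p[ii] * s[ii], `+`)) /
          outer(p[ii], p[ii], `+`)) / Nv
  } else 0
  strength_num <- sum(outer(p[ii], p[ii], `+`) * outer(ii, ii, `-`)^2)
  strength <- if (sum(s) > 0) strength_num / sum(s) else 0
  c(ngtdm_coarseness = coars, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Full static feature vector
#'
#' Concatenates shape (14), first-order (22), GLCM (24), GLRLM (16),
#' GLSZM (16), GLDM (14) and NGTDM (5) into the fixed 111-entry static
#' catalog. Intensity and texture families are computed on the first
#' post-contrast phase after 8-bit rescaling and fixed-bin-width
#' quantization.
#'
#' @param study A [dce_study()].
#' @param bits,bin_width Quantization settings (defaults 8 and 25).
#' @return Named numeric vector of 111 finite values in catalog order.
#' @export
static_feature_vector <- function(study, bits = 8, bin_width = 25) {
  study <- crop_to_mask(study)
  roi <- rescale_quantize(study$phases[[2]], study$mask, bits, bin_width)
  out <- c(shape_features(study$mask, study$spacing),
           first_order_features(study, roi),
           texture_matrix_features(roi, "GLCM"),
           texture_matrix_features(roi, "GLRLM"),
           texture_matrix_features(roi, "GLSZM"),
           texture_matrix_features(roi, "GLDM"),
           texture_matrix_features(roi, "NGTDM"))
  stopifnot(identical(names(out), static_feature_catalog()),
            all(is.finite(out)))
  out
}
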