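#' Per-voxel semi-quantitative kinetic parameters
#'
#' Converts a four-point signal curve into the standard semi-quantitative
#' DCE parameters. Enhancement is baseline-relative,
#' `E_t = (S_t - S_0) / max(S_0, eps)` with `E_0 = 0`; then
#' `PE = max_t E_t` (peak enhancement), `TTP` is the time of the first
#' maximizer minus the pre-contrast time, `WIS = PE / TTP` (wash-in slope)
#' and `WOS = (E_last - E_peak) / (t_last - t_peak)` when the peak precedes
#' the last phase, else 0 (wash-out slope). Flat curves peak by convention at
#' the first post-contrast phase with `WIS = 0`.
#'
#' @param signal Numeric length-4 intensities (pre, post1..post3).
#' @param times Numeric length-4 acquisition times in minutes.
#' @param eps Baseline guard: the divisor is `max(S_0, eps)` (default 1
#'   intensity unit), so non-positive baselines never blow up.
#' @return Named list with `PE`, `TTP` (minutes), `WIS`, `WOS` (per minute).
#' @export
#' @examples
#' voxel_kinetics(c(100, 200, 180, 160), c(0, 1, 2, 3))
voxel_kinetics <- function(signal, times, eps = 1) {
  stopifnot(length(signal) == 4L, length(times) == 4L, all(diff(times) > 0))
  e <- (signal - signal[1]) / max(signal[1], eps)
  e[1] <- 0
  post <- e[-1]
  peak <- which.max(post)                  # first maximizer
  pe <- post[peak]
  if (all(post == post[1]) && post[1] == 0) peak <- 1L   # flat convention
  ttp <- times[peak + 1L] - times[1]
  wis <- pe / ttp
  wos <- if (peak < 3L) (post[3] - pe) / (times[4] - times[peak + 1L]) else 0
  list(PE = pe, TTP = ttp, WIS = wis, WOS = wos)
}

#' Voxelwise kinetic parameter maps
#'
#' Vectorized [voxel_kinetics()] over every in-mask voxel of a study, plus
#' the peak-phase map used for the TTP partition.
#'
#' @param study A [dce_study()].
#' @param eps Baseline guard passed to the enhancement computation. Lesions
#'   containing non-positive baselines are flagged once via `message()`.
#' @return List of 3D arrays `PE`, `TTP`, `WIS`, `WOS` (NA outside the
#'   mask) and `peak_phase` (integer 1..3, NA outside).
#' @export
kinetic_param_maps <- function(study, eps = 1) {
  stopifnot(inherits(study, "dce_study"))
  inmask <- study$mask == 1L
  s0 <- study$phases[[1]][inmask]
  if (any(s0 <= 0))
    message("lesion ", study$lesion_id, ": ", sum(s0 <= 0),
            " voxel(s) with non-positive baseline; eps guard applied")
  base <- pmax(s0, eps)
  E <- vapply(2:4, function(k) (study$phases[[k]][inmask] - s0) / base,
              numeric(sum(inmask)))
  E <- matrix(E, ncol = 3)
  peak <- max.col(E, ties.method = "first")
  n <- nrow(E)
  pe <- E[cbind(seq_len(n), peak)]
  t_post <- study$times[2:4]
  ttp <- t_post[peak] - study$times[1]
  wis <- pe / ttp
  wos <- ifelse(peak < 3L,
                (E[, 3] - pe) / (study$times[4] - t_post[peak]), 0)
  dims <- dim(study$mask)
  as_map <- function(v) { m <- array(NA_real_, dims); m[inmask] <- v; m }
  pp <- array(NA_integer_, dims); pp[inmask] <- peak
  list(PE = as_map(pe), TTP = as_map(ttp), WIS = as_map(wis),
       WOS = as_map(wos), peak_phase = pp)
}

#' Aggregate kinetic features
#'
#' The 10 lesion-level summaries of the voxelwise kinetics: mean and SD of
#' WIS, WOS, PE and TTP, the maximum PE over the lesion (MPE), and the hot
#' spot — the highest mean PE over any in-mask 26-connected 3x3x3
#' neighbourhood.
#'
#' @param study A [dce_study()].
#' @param maps Optional precomputed [kinetic_param_maps()].
#' @return Named numeric vector of 10 values (`kin_agg_*`).
#' @export
aggregate_features <- function(study, maps = kinetic_param_maps(study)) {
  inmask <- study$mask == 1L
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  out <- c(
    kin_agg_wis_mean = mean(maps$WIS[inmask]),
    kin_agg_wis_sd   = sd0(maps$WIS[inmask]),
    kin_agg_wos_mean = mean(maps$WOS[inmask]),
    kin_agg_wos_sd   = sd0(maps$WOS[inmask]),
    kin_agg_pe_mean  = mean(maps$PE[inmask]),
    kin_agg_pe_sd    = sd0(maps$PE[inmask]),
    kin_agg_ttp_mean = mean(maps$TTP[inmask]),
    kin_agg_ttp_sd   = sd0(maps$TTP[inmask]),
    kin_agg_mpe      = max(maps$PE[inmask]),
    kin_agg_hotspot  = hotspot_pe(maps$PE, study$mask))
  out
}

# highest mean PE over the 3x3x3 neighbourhood (26-connectivity, centre
# included) intersected with the mask, over all in-mask centres
hotspot_pe <- function(pe_map, mask) {
  d <- dim(mask)
  dp <- d + 2L
  pep <- array(NA_real_, dp)
  pep[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- pe_map
  offs <- rbind(c(0, 0, 0), offsets26())
  deltas <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  centers <- which(!is.na(pep))
  ssum <- numeric(length(centers)); cnt <- integer(length(centers))
  for (dl in deltas) {
    nb <- pep[centers + dl]
    ok <- !is.na(nb)
    ssum[ok] <- ssum[ok] + nb[ok]
    cnt <- cnt + as.integer(ok)
  }
  max(ssum / cnt)
}

#' Time-to-peak characteristic map
#'
#' Partitions the in-mask voxels into three sub-clusters by their TTP:
#' with three post-contrast phases a voxel peaks at post-phase 1, 2 or 3,
#' labelled quick, intermediate and slow arrival respectively.
#'
#' @param study A [dce_study()].
#' @param maps Optional precomputed [kinetic_param_maps()].
#' @return An object of class `ttp_map`: `labels` (3D array with values
#'   `"quick"`, `"intermediate"`, `"slow"`, NA outside the mask) and
#'   `proportions` (named simplex triple).
#' @export
ttp_partition <- function(study, maps = kinetic_param_maps(study)) {
  lv <- c("quick", "intermediate", "slow")
  labels <- array(NA_character_, dim(study$mask))
  inmask <- study$mask == 1L
  labels[inmask] <- lv[maps$peak_phase[inmask]]
  counts <- vapply(lv, function(l) sum(labels == l, na.rm = TRUE), numeric(1))
  structure(list(labels = labels, proportions = counts / sum(counts)),
            class = "ttp_map")
}

#' Heterogeneity kinetic features
#'
#' Per TTP sub-cluster: mean and SD of WIS, WOS and PE (18 values) plus the
#' three sub-cluster proportions — 21 features. An empty sub-cluster
#' contributes zeros.
#'
#' @param study A [dce_study()].
#' @param map A [ttp_partition()] computed from the same study.
#' @param maps Optional precomputed [kinetic_param_maps()].
#' @return Named numeric vector of 21 values (`kin_het_*`).
#' @export
heterogeneity_features <- function(study, map = ttp_partition(study, maps),
                                   maps = kinetic_param_maps(study)) {
  out <- numeric(0)
  for (cl in c("quick", "intermediate", "slow")) {
    sel <- !is.na(map$labels) & map$labels == cl
    stat <- function(m) {
      v <- m[sel]
      if (!length(v)) c(0, 0)
      else c(mean(v), if (length(v) > 1L) stats::sd(v) else 0)
    }
    vals <- c(stat(maps$WIS), stat(maps$WOS), stat(maps$PE),
              unname(map$proportions[cl]))
    names(vals) <- paste0("kin_het_", cl, "_",
                          c("wis_mean", "wis_sd", "wos_mean", "wos_sd",
                            "pe_mean", "pe_sd", "prop"))
    out <- c(out, vals)
  }
  out
}

#' Textural-kinetic features
#'
#' Texture descriptors of the spatial arrangement of the kinetic parameter
#' maps. Each of WIS, WOS and PE is quantized in-mask to `levels` equal-width
#' bins, a symmetric normalized 3D co-occurrence matrix is averaged over the
#' 13 distance-1 offsets, and 19 descriptors are emitted per map: the 13
#' classic co-occurrence statistics (ASM, contrast, correlation, variance,
#' IDM, sum average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, IMC1, IMC2), the absolute value of differences
#' (AVD, the mean level difference of co-occurring pairs), and 5 in-mask
#' histogram statistics (mean, SD, skewness, kurtosis, entropy) — 57 in all.
#'
#' @param study A [dce_study()].
#' @param map A [ttp_partition()] (kept in the signature so callers can
#'   reuse it; the descriptors are functions of the parameter maps).
#' @param levels Number of quantization levels (default 11).
#' @param maps Optional precomputed [kinetic_param_maps()].
#' @return Named numeric vector of 57 values (`kin_tex_*`).
#' @export
textural_kinetic_features <- function(study, map = NULL, levels = 11L,
                                      maps = kinetic_param_maps(study)) {
  if (levels < 2) stop("`levels` must be >= 2")
  out <- numeric(0)
  for (mp in c("wis", "wos", "pe")) {
    pm <- maps[[toupper(mp)]]
    q <- quantize_map(pm, study$mask, levels)
    P <- glcm_matrix(q$levels, q$n_levels)
    har <- haralick13(P)
    hist <- hist_stats(q$levels[study$mask == 1L], q$n_levels)
    vals <- c(har, avd = sum(P * abs(row(P) - col(P))), hist)
    names(vals) <- paste0("kin_tex_", mp, "_", names(vals))
    out <- c(out, vals)
  }
  out
}

# 13 classic co-occurrence descriptors from a normalized symmetric matrix
haralick13 <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  log2p <- function(x) ifelse(x > 0, log2(x), 0)
  # p_{x+y}(k), k = 2..2L and p_{x-y}(k), k = 0..L-1
  pxy_sum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  sa <- sum((2:(2 * L)) * pxy_sum)
  da <- sum((0:(L - 1)) * pxy_dif)
  hx <- -sum(px * log2p(px)); hy <- -sum(py * log2p(py))
  hxy <- -sum(P * log2p(P))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2p(pxpy))
  hxy2 <- -sum(pxpy * log2p(pxpy))
  imc2arg <- 1 - exp(-2 * (hxy2 - hxy))
  c(asm = sum(P^2),
    contrast = sum(P * (i - j)^2),
    correlation = if (sx > 0 && sy > 0)
      sum((i - mux) * (j - muy) * P) / (sx * sy) else 0,
    variance = sum((i - mux)^2 * P),
    idm = sum(P / (1 + (i - j)^2)),
    sum_average = sa,
    sum_variance = sum(((2:(2 * L)) - sa)^2 * pxy_sum),
    sum_entropy = -sum(pxy_sum * log2p(pxy_sum)),
    entropy = hxy,
    difference_variance = sum(((0:(L - 1)) - da)^2 * pxy_dif),
    difference_entropy = -sum(pxy_dif * log2p(pxy_dif)),
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(imc2arg, 0)))
}

# first-four-moment + entropy statistics of quantized in-mask levels
hist_stats <- function(lev_in, L) {
  m <- mean(lev_in); s <- stats::sd(lev_in)
  if (length(lev_in) < 2L || is.na(s)) s <- 0
  ctr <- lev_in - m
  skw <- if (s > 0) mean(ctr^3) / (sqrt(mean(ctr^2)))^3 else 0
  krt <- if (s > 0) mean(ctr^4) / (mean(ctr^2))^2 else 0
  p <- tabulate(lev_in, nbins = L) / length(lev_in)
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  c(hist_mean = m, hist_sd = s, hist_skewness = skw,
    hist_kurtosis = krt, hist_entropy = ent)
}

#' Full kinetic feature vector
#'
#' Concatenates the aggregate (10), heterogeneity (21) and textural-kinetic
#' (57) groups into the fixed 88-entry kinetic catalog.
#'
#' @param study A [dce_study()].
#' @param levels Quantization levels for the textural-kinetic group.
#' @return Named numeric vector of 88 finite values in catalog order.
#' @export
kinetic_feature_vector <- function(study, levels = 11L) {
  study <- crop_to_mask(study)
  maps <- kinetic_param_maps(study)
  map <- ttp_partition(study, maps)
  out <- c(aggregate_features(study, maps),
           heterogeneity_features(study, map, maps),
           textural_kinetic_features(study, map, levels, maps))
  stopifnot(identical(names(out), kinetic_feature_catalog()),
            all(is.finite(out)))
  out
}
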