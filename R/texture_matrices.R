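# Gray-level matrix machinery shared by the static texture families and the
# textural-kinetic descriptors. All builders take a 3D integer array `lev`
# with levels 1..n_levels inside the ROI and NA outside, and work on the
# full (already cropped) grid.

# the 13 unique distance-1 offsets of a 3D grid (half of the 26 neighbours),
# in a fixed canonical order: axes, face diagonals, space diagonals
offsets13 <- function() {
  matrix(c(1, 0, 0,   0, 1, 0,   0, 0, 1,
           1, 1, 0,   1, -1, 0,  1, 0, 1,  1, 0, -1,
           0, 1, 1,   0, 1, -1,
           1, 1, 1,   1, 1, -1,  1, -1, 1, 1, -1, -1),
         ncol = 3, byrow = TRUE)
}

# all 26 neighbour offsets
offsets26 <- function() {
  o <- offsets13()
  rbind(o, -o)
}

#' Rescale and quantize a region of interest
#'
#' Min–max rescales the in-mask intensities to `[0, 2^bits - 1]` and bins
#' them with a fixed bin width, the discretization used for all static
#' texture families (8 bits and bin width 25 give at most 11 gray levels).
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array of the same shape.
#' @param bits Bit depth of the rescale (default 8).
#' @param bin_width Fixed bin width on the rescaled intensities (default 25).
#' @return A list of class `quantized_roi`: `levels` (3D integer array, NA
#'   outside the mask), `n_levels`, `bin_width`, `bits`.
#' @export
rescale_quantize <- function(volume, mask, bits = 8, bin_width = 25) {
  stopifnot(identical(dim(volume), dim(mask)))
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  inmask <- mask != 0
  if (!any(inmask)) stop("mask is empty")
  v <- volume[inmask]
  rng <- range(v)
  if (rng[2] > rng[1]) {
    resc <- (v - rng[1]) / (rng[2] - rng[1]) * (2^bits - 1)
  } else {
    resc <- rep(0, length(v))          # constant ROI collapses to one level
  }
  lev_in <- as.integer(floor(resc / bin_width)) + 1L
  lev <- array(NA_integer_, dim(volume))
  lev[inmask] <- lev_in
  structure(list(levels = lev, n_levels = max(lev_in),
                 bin_width = bin_width, bits = bits),
            class = "quantized_roi")
}

# quantize a numeric parameter map (e.g. WIS/WOS/PE) to equal-width bins
# between its in-mask min and max; `levels` bins, constant map -> 1 level
quantize_map <- function(map, mask, levels = 11L) {
  if (levels < 2) stop("`levels` must be >= 2")
  inmask <- mask != 0
  v <- map[inmask]
  rng <- range(v)
  if (rng[2] > rng[1]) {
    lev_in <- pmin(as.integer(floor((v - rng[1]) / (rng[2] - rng[1]) * levels)) + 1L,
                   as.integer(levels))
    nl <- as.integer(levels)
  } else {
    lev_in <- rep(1L, length(v))
    nl <- 1L
  }
  lev <- array(NA_integer_, dim(map))
  lev[inmask] <- lev_in
  list(levels = lev, n_levels = nl)
}

# pair counts for one offset; returns L x L matrix of ordered-pair counts
glcm_pairs_offset <- function(lev, off, L) {
  d <- dim(lev)
  i1 <- seq_len(d[1] - abs(off[1])); i2 <- seq_len(d[2] - abs(off[2]))
  i3 <- seq_len(d[3] - abs(off[3]))
  if (!length(i1) || !length(i2) || !length(i3))
    return(matrix(0, L, L))
  a <- lev[i1 + max(0,  off[1]), i2 + max(0,  off[2]), i3 + max(0,  off[3]), drop = FALSE]
  b <- lev[i1 + max(0, -off[1]), i2 + max(0, -off[2]), i3 + max(0, -off[3]), drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, L, L))
  matrix(tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L), L, L, byrow = TRUE)
}

# symmetric normalized co-occurrence matrix, averaged over the 13 offsets
# (offsets with no valid pair are skipped)
glcm_matrix <- function(lev, L) {
  offs <- offsets13()
  acc <- matrix(0, L, L)
  used <- 0L
  for (r in seq_len(nrow(offs))) {
    cnt <- glcm_pairs_offset(lev, offs[r, ], L)
    cnt <- cnt + t(cnt)
    s <- sum(cnt)
    if (s > 0) { acc <- acc + cnt / s; used <- used + 1L }
  }
  if (used == 0L) matrix(1, 1, 1) else acc / used
}

# run-length matrices, one per direction; returns list of count matrices
# (levels x run length)
glrlm_matrices <- function(lev, L) {
  d <- dim(lev)
  co <- arrayInd(seq_len(prod(d)), d)
  offs <- offsets13()
  maxrun <- max(d)
  lapply(seq_len(nrow(offs)), function(r) {
    dir <- offs[r, ]
    t_along <- co %*% dir                       # strictly monotone along the line
    keyv <- co * sum(dir^2) - as.vector(t_along) %*% t(dir)
    key <- keyv[, 1] + (keyv[, 2] + 3 * max(d)) * (9 * max(d)) +
      (keyv[, 3] + 3 * max(d)) * (9 * max(d))^2
    ord <- order(key, t_along)
    lv <- as.vector(lev)[ord]
    newline <- c(TRUE, diff(key[ord]) != 0)
    # a run breaks at a new line, a level change, or an NA boundary
    lvc <- ifelse(is.na(lv), -1L, lv)
    brk <- newline | c(TRUE, lvc[-1] != lvc[-length(lvc)])
    run_id <- cumsum(brk)
    len <- tabulate(run_id)
    first <- which(brk)
    run_lev <- lvc[first]
    ok <- run_lev > 0L
    m <- matrix(0, L, maxrun)
    if (any(ok)) {
      tb <- tabulate((run_lev[ok] - 1L) * maxrun + len[ok], nbins = L * maxrun)
      m <- matrix(tb, L, maxrun, byrow = TRUE)
    }
    m
  })
}

# 26-connected components of equal-level in-mask voxels -> zone size counts;
# returns matrix levels x max zone size
glszm_matrix <- function(lev, L) {
  d <- dim(lev)
  n <- prod(d)
  offs <- offsets26()
  # linear-index neighbour deltas are only valid away from borders; pad instead
  dp <- d + 2L
  levp <- array(NA_integer_, dp)
  levp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lev
  deltas <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  unvisited <- !is.na(levp)
  zones <- list()
  todo <- which(unvisited)
  for (start in todo) {
    if (!unvisited[start]) next
    lv <- levp[start]
    comp <- integer(0)
    frontier <- start
    unvisited[start] <- FALSE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      nb <- unique(as.vector(outer(frontier, deltas, `+`)))
      nb <- nb[unvisited[nb] & levp[nb] == lv]
      nb <- nb[!is.na(nb)]
      unvisited[nb] <- FALSE
      frontier <- nb
    }
    zones[[length(zones) + 1L]] <- c(lv, length(comp))
  }
  zs <- do.call(rbind, zones)
  smax <- max(zs[, 2])
  m <- matrix(0, L, smax)
  for (r in seq_len(nrow(zs))) m[zs[r, 1], zs[r, 2]] <- m[zs[r, 1], zs[r, 2]] + 1
  m
}

# gray-level dependence matrix: dependence of a voxel = 1 + number of in-mask
# 26-neighbours whose level differs by at most `alpha` (the voxel always
# depends on itself); returns matrix levels x 27
gldm_matrix <- function(lev, L, alpha = 0) {
  d <- dim(lev)
  dp <- d + 2L
  levp <- array(NA_integer_, dp)
  levp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lev
  offs <- offsets26()
  deltas <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  centers <- which(!is.na(levp))
  dep <- rep(1L, length(centers))
  for (dl in deltas) {
    nb <- levp[centers + dl]
    dep <- dep + as.integer(!is.na(nb) & abs(nb - levp[centers]) <= alpha)
  }
  m <- matrix(0, L, 27L)
  tb <- tabulate((levp[centers] - 1L) * 27L + dep, nbins = L * 27L)
  matrix(tb, L, 27L, byrow = TRUE)
}

# neighbourhood gray-tone difference matrix ingredients: for each level i,
# n_i (count of valid voxels) and s_i (summed absolute difference from the
# mean level of the in-mask 26-neighbourhood); voxels with no in-mask
# neighbour are excluded
ngtdm_matrix <- function(lev, L) {
  d <- dim(lev)
  dp <- d + 2L
  levp <- array(NA_integer_, dp)
  levp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lev
  offs <- offsets26()
  deltas <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  centers <- which(!is.na(levp))
  nsum <- numeric(length(centers)); ncnt <- integer(length(centers))
  for (dl in deltas) {
    nb <- levp[centers + dl]
    ok <- !is.na(nb)
    nsum[ok] <- nsum[ok] + nb[ok]
    ncnt <- ncnt + as.integer(ok)
  }
  valid <- ncnt > 0L
  lv <- levp[centers][valid]
  diffs <- abs(lv - nsum[valid] / ncnt[valid])
  n_i <- tabulate(lv, nbins = L)
  s_i <- vapply(seq_len(L), function(i) sum(diffs[lv == i]), numeric(1))
  list(n = n_i, s = s_i, n_valid = sum(valid))
}
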