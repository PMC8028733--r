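#' Shape features of the tumor mask
#'
#' Fourteen 3D shape descriptors in physical units: voxel volume, mesh
#' volume and mesh surface area (from a marching-tetrahedra isosurface of
#' the binary mask), surface-to-volume ratio, sphericity, compactness,
#' spherical disproportion, maximum 3D diameter, the three principal axis
#' lengths (from the PCA of in-mask voxel coordinates), elongation,
#' flatness, and extent (voxel volume over bounding-box volume).
#'
#' @param mask 3D binary array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return Named numeric vector of 14 values (`shape_*`).
#' @export
shape_features <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L)
  idx <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 1L) stop("mask is empty")
  vox_vol <- n * prod(spacing)

  if (n == 1L) {
    # degenerate single voxel: surface of the voxel cuboid, zero axes
    a <- spacing[1]; b <- spacing[2]; c_ <- spacing[3]
    area <- 2 * (a * b + b * c_ + a * c_)
    mesh_vol <- vox_vol
    axes <- c(0, 0, 0)
  } else {
    mesh <- marching_tetrahedra(mask, spacing)
    area <- mesh$area
    mesh_vol <- mesh$volume
    co <- sweep(idx, 2, spacing, `*`)
    ev <- sort(eigen(stats::cov(co), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes <- 4 * sqrt(ev)
  }
  sph <- (36 * pi * mesh_vol^2)^(1 / 3) / area
  bbox <- apply(idx, 2, function(v) diff(range(v)) + 1)
  c(shape_voxel_volume = vox_vol,
    shape_mesh_volume = mesh_vol,
    shape_surface_area = area,
    shape_surface_volume_ratio = area / mesh_vol,
    shape_sphericity = sph,
    shape_compactness = 36 * pi * mesh_vol^2 / area^3,
    shape_spherical_disproportion = 1 / sph,
    shape_max_3d_diameter = max_3d_diameter(idx, spacing),
    shape_major_axis_length = axes[1],
    shape_minor_axis_length = axes[2],
    shape_least_axis_length = axes[3],
    shape_elongation = if (axes[1] > 0) axes[2] / axes[1] else 0,
    shape_flatness = if (axes[1] > 0) axes[3] / axes[1] else 0,
    shape_extent = n / prod(bbox))
}

# largest pairwise Euclidean distance between boundary voxel centres
max_3d_diameter <- function(idx, spacing) {
  co <- sweep(idx, 2, spacing, `*`)
  if (nrow(co) > 200L) {
    # restrict to boundary voxels (some 6-neighbour outside the mask)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    all_keys <- key(idx)
    inside <- rep(TRUE, nrow(idx))
    for (d in 1:3) for (s in c(-1L, 1L)) {
      nb <- idx; nb[, d] <- nb[, d] + s
      inside <- inside & key(nb) %in% all_keys
    }
    co <- co[!inside, , drop = FALSE]
  }
  m <- nrow(co)
  if (m == 1L) return(0)
  dmax <- 0
  chunk <- 500L
  for (st in seq(1L, m, by = chunk)) {
    en <- min(st + chunk - 1L, m)
    block <- co[st:en, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(co^2), `+`) -
      2 * block %*% t(co)
    dmax <- max(dmax, max(d2))
  }
  sqrt(max(dmax, 0))
}

# Marching tetrahedra over the 0.5-isosurface of the mask indicator,
# mollified with a 3x3x3 box filter so that interpolated vertex placement
# tracks the underlying smooth boundary (a midpoint staircase surface
# overestimates area). Thin masks that vanish under mollification fall back
# to the binary midpoint surface. Each grid cube is split into 6 tetrahedra
# (Kuhn decomposition, face-conforming across cubes); triangles are
# oriented outward so the signed divergence sum gives the enclosed volume.
marching_tetrahedra <- function(mask, spacing, mollify = TRUE) {
  d <- dim(mask)
  pad <- 2L
  m <- array(0, d + 2L * pad)
  m[pad + (1:d[1]), pad + (1:d[2]), pad + (1:d[3])] <- as.numeric(mask != 0)
  if (mollify) {
    dp0 <- dim(m)
    f <- array(0, dp0)
    for (o1 in -1:1) for (o2 in -1:1) for (o3 in -1:1) {
      i1 <- pmin(pmax(1:dp0[1] + o1, 1), dp0[1])
      i2 <- pmin(pmax(1:dp0[2] + o2, 1), dp0[2])
      i3 <- pmin(pmax(1:dp0[3] + o3, 1), dp0[3])
      f <- f + m[i1, i2, i3]
    }
    f <- f / 27
    if (!any(f >= 0.5))                       # mask too thin to mollify
      return(marching_tetrahedra(mask, spacing, mollify = FALSE))
    m <- f
  }
  dp <- dim(m)
  # corner offsets of a cube, in voxel coordinates
  corn <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  # 6-tetrahedra decomposition along the main diagonal c0-c7
  # corners indexed 1..8 in the expand.grid order above
  cid <- function(x, y, z) 1L + x + 2L * y + 4L * z
  tets <- rbind(
    c(cid(0,0,0), cid(1,0,0), cid(1,1,0), cid(1,1,1)),
    c(cid(0,0,0), cid(1,0,0), cid(1,0,1), cid(1,1,1)),
    c(cid(0,0,0), cid(0,1,0), cid(1,1,0), cid(1,1,1)),
    c(cid(0,0,0), cid(0,1,0), cid(0,1,1), cid(1,1,1)),
    c(cid(0,0,0), cid(0,0,1), cid(1,0,1), cid(1,1,1)),
    c(cid(0,0,0), cid(0,0,1), cid(0,1,1), cid(1,1,1)))
  inside_arr <- m >= 0.5
  # cube origins with a mixed corner classification (surface cubes only)
  csum <- array(0L, dp - 1L)
  for (r in seq_len(8)) {
    csum <- csum + inside_arr[(1:(dp[1] - 1)) + corn[r, 1],
                              (1:(dp[2] - 1)) + corn[r, 2],
                              (1:(dp[3] - 1)) + corn[r, 3], drop = FALSE]
  }
  mixed <- which(csum > 0L & csum < 8L, arr.ind = TRUE)
  area <- 0
  vol6 <- 0
  if (nrow(mixed)) {
    for (r in seq_len(nrow(mixed))) {
      org <- as.numeric(mixed[r, ])
      cpos <- sweep(corn, 2, org, `+`)               # voxel coords of corners
      vals <- m[cpos]
      pxyz <- sweep(cpos, 2, spacing, `*`)           # physical coords
      for (tt in seq_len(6)) {
        vid <- tets[tt, ]
        v <- vals[vid]
        ins <- which(v >= 0.5); outs <- which(v < 0.5)
        ni <- length(ins)
        if (ni == 0L || ni == 4L) next
        P <- pxyz[vid, , drop = FALSE]
        mid <- function(a, b) {
          t <- (0.5 - v[a]) / (v[b] - v[a])   # linear interpolation on the edge
          P[a, ] + t * (P[b, ] - P[a, ])
        }
        inside_ctr <- colMeans(P[ins, , drop = FALSE])
        tris <- list()
        if (ni == 1L || ni == 3L) {
          a <- if (ni == 1L) ins else outs
          oth <- if (ni == 1L) outs else ins
          tris[[1]] <- rbind(mid(a, oth[1]), mid(a, oth[2]), mid(a, oth[3]))
        } else {  # 2 inside: quad split into 2 triangles
          m11 <- mid(ins[1], outs[1]); m12 <- mid(ins[1], outs[2])
          m22 <- mid(ins[2], outs[2]); m21 <- mid(ins[2], outs[1])
          tris[[1]] <- rbind(m11, m12, m22)
          tris[[2]] <- rbind(m11, m22, m21)
        }
        for (tri in tris) {
          e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
          nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
                   e1[3] * e2[1] - e1[1] * e2[3],
                   e1[1] * e2[2] - e1[2] * e2[1])
          # orient outward: away from the inside corners of this tet
          if (sum(nrm * (colMeans(tri) - inside_ctr)) < 0) {
            tri <- tri[c(1, 3, 2), ]
            nrm <- -nrm
          }
          area <- area + sqrt(sum(nrm^2)) / 2
          vol6 <- vol6 + sum(tri[1, ] * c(
            tri[2, 2] * tri[3, 3] - tri[2, 3] * tri[3, 2],
            tri[2, 3] * tri[3, 1] - tri[2, 1] * tri[3, 3],
            tri[2, 1] * tri[3, 2] - tri[2, 2] * tri[3, 1]))
        }
      }
    }
  }
  list(area = area, volume = abs(vol6) / 6)
}
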