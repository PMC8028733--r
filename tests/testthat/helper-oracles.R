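# Independent brute-force oracles. These deliberately avoid the package's
# vectorized builders: everything is computed by direct enumeration of voxel
# pairs, runs, zones and neighbourhoods so the two routes share no code.

oracle_offsets13 <- function() {
  list(c(1,0,0), c(0,1,0), c(0,0,1),
       c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
       c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
}

oracle_at <- function(lev, p) {
  d <- dim(lev)
  if (any(p < 1) || any(p > d)) return(NA_integer_)
  lev[p[1], p[2], p[3]]
}

# symmetric normalized co-occurrence matrix averaged over offsets
oracle_glcm <- function(lev, L) {
  d <- dim(lev)
  acc <- matrix(0, L, L); used <- 0
  for (off in oracle_offsets13()) {
    cnt <- matrix(0, L, L)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      a <- lev[i, j, k]
      if (is.na(a)) next
      b <- oracle_at(lev, c(i, j, k) + off)
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    if (sum(cnt) > 0) { acc <- acc + cnt / sum(cnt); used <- used + 1 }
  }
  if (used == 0) matrix(1, 1, 1) else acc / used
}

# run-length matrix for one direction by walking each maximal run
oracle_glrlm_one <- function(lev, L, off) {
  d <- dim(lev)
  maxrun <- max(d)
  R <- matrix(0, L, maxrun)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    prev <- oracle_at(lev, c(i, j, k) - off)
    if (!is.na(prev) && prev == a) next       # not the start of a run
    len <- 1
    p <- c(i, j, k) + off
    while (!is.na(nb <- oracle_at(lev, p)) && nb == a) {
      len <- len + 1
      p <- p + off
    }
    R[a, len] <- R[a, len] + 1
  }
  R
}

oracle_glrlm <- function(lev, L) lapply(oracle_offsets13(),
                                        function(o) oracle_glrlm_one(lev, L, o))

# zones by repeated set dilation over the 26-neighbourhood
oracle_glszm <- function(lev, L) {
  d <- dim(lev)
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  keyf <- function(m) m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
  zones <- list()
  remaining <- which(!is.na(lev), arr.ind = TRUE)
  taken <- rep(FALSE, prod(d))
  for (r in seq_len(nrow(remaining))) {
    p <- remaining[r, ]
    if (taken[keyf(matrix(p, 1))]) next
    lv <- lev[p[1], p[2], p[3]]
    comp <- matrix(p, 1)
    taken[keyf(comp)] <- TRUE
    grew <- TRUE
    while (grew) {
      grew <- FALSE
      for (ci in seq_len(nrow(comp))) for (oi in seq_len(nrow(offs))) {
        q <- comp[ci, ] + as.numeric(offs[oi, ])
        if (any(q < 1) || any(q > d)) next
        kq <- keyf(matrix(q, 1))
        if (taken[kq]) next
        lq <- lev[q[1], q[2], q[3]]
        if (!is.na(lq) && lq == lv) {
          comp <- rbind(comp, q)
          taken[kq] <- TRUE
          grew <- TRUE
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lv, nrow(comp))
  }
  zs <- do.call(rbind, zones)
  m <- matrix(0, L, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) m[zs[r, 1], zs[r, 2]] <- m[zs[r, 1], zs[r, 2]] + 1
  m
}

# dependence matrix: 1 + count of 26-neighbours with equal level (alpha = 0)
oracle_gldm <- function(lev, L, alpha = 0) {
  d <- dim(lev)
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  D <- matrix(0, L, 27)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    dep <- 1
    for (oi in seq_len(nrow(offs))) {
      b <- oracle_at(lev, c(i, j, k) + as.numeric(offs[oi, ]))
      if (!is.na(b) && abs(b - a) <= alpha) dep <- dep + 1
    }
    D[a, dep] <- D[a, dep] + 1
  }
  D
}

oracle_ngtdm <- function(lev, L) {
  d <- dim(lev)
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  n <- numeric(L); s <- numeric(L); nval <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    nb <- c()
    for (oi in seq_len(nrow(offs))) {
      b <- oracle_at(lev, c(i, j, k) + as.numeric(offs[oi, ]))
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    nval <- nval + 1
    n[a] <- n[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(n = n, s = s, n_valid = nval)
}

# highest neighbourhood-mean PE by direct enumeration
oracle_hotspot <- function(pe_map, mask) {
  d <- dim(mask)
  best <- -Inf
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    vals <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      p <- c(i + di, j + dj, k + dk)
      if (any(p < 1) || any(p > d)) next
      if (mask[p[1], p[2], p[3]] == 1) vals <- c(vals, pe_map[p[1], p[2], p[3]])
    }
    best <- max(best, mean(vals))
  }
  best
}

# BH step-up by its definition: q_i = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# AUC by positive-negative pair counting (ties count 1/2)
oracle_auc <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  u <- 0
  for (a in pos) for (b in neg)
    u <- u + if (a > b) 1 else if (a == b) 0.5 else 0
  u / (length(pos) * length(neg))
}

# direct-formula first-order statistics for a numeric vector
oracle_first_order <- function(x) {
  n <- length(x)
  m <- mean(x)
  c(mean = m, median = median(x), min = min(x), max = max(x),
    range = max(x) - min(x),
    variance = sum((x - m)^2) / n,
    mad = sum(abs(x - m)) / n,
    rms = sqrt(sum(x^2) / n),
    energy = sum(x^2),
    skewness = (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5,
    kurtosis = (sum((x - m)^4) / n) / (sum((x - m)^2) / n)^2)
}
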