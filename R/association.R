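#' Univariate feature-abundance association scan
#'
#' For every (radiomic feature, cell population) pair, fits the simple
#' linear regression of abundance on the feature and records the slope, the
#' Pearson correlation, the two-sided t-test p-value on the slope (equal to
#' the Pearson correlation test p-value), and the BH-adjusted p-value.
#'
#' @param features Lesions x features numeric matrix (rownames = sample
#'   IDs matching the abundance table).
#' @param abundance An `abundance_table` from [score_abundance()].
#' @param adjust_within `"all"` (default: one BH family over every pair) or
#'   `"population"` (adjust within each population separately).
#' @return Data frame with columns `feature`, `population`, `slope`, `r`,
#'   `p`, `p_adj`, `note` (`"zero_variance"` rows carry NA statistics and
#'   are excluded from the BH family).
#' @export
univariate_scan <- function(features, abundance,
                            adjust_within = c("all", "population")) {
  adjust_within <- match.arg(adjust_within)
  stopifnot(inherits(abundance, "abundance_table"))
  common <- intersect(rownames(features), rownames(abundance$scores))
  if (length(common) < 4L)
    stop("need >= 4 common samples for the association scan (have ",
         length(common), ")")
  X <- features[common, , drop = FALSE]
  A <- abundance$scores[common, , drop = FALSE]
  n <- length(common)
  zerovar <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(zerovar))
    warning(sum(zerovar), " zero-variance feature(s) skipped: ",
            paste(utils::head(colnames(X)[zerovar], 5), collapse = ", "))
  res <- expand.grid(feature = colnames(X), population = colnames(A),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$slope <- NA_real_; res$r <- NA_real_; res$p <- NA_real_
  res$note <- ifelse(zerovar[res$feature], "zero_variance", "")
  ok <- res$note == ""
  # vectorized simple-regression statistics across all pairs
  Xc <- scale(X, scale = FALSE); Ac <- scale(A, scale = FALSE)
  sxx <- colSums(Xc^2); syy <- colSums(Ac^2)
  sxy <- t(Xc) %*% Ac                          # features x populations
  slope <- sxy / sxx
  r <- sxy / sqrt(outer(sxx, syy))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  idx <- cbind(match(res$feature, colnames(X)),
               match(res$population, colnames(A)))
  res$slope[ok] <- slope[idx[ok, , drop = FALSE]]
  res$r[ok] <- r[idx[ok, , drop = FALSE]]
  res$p[ok] <- p[idx[ok, , drop = FALSE]]
  res$p_adj <- NA_real_
  if (adjust_within == "all") {
    res$p_adj[ok] <- bh_adjust(res$p[ok])
  } else {
    for (pop in unique(res$population)) {
      sel <- ok & res$population == pop
      res$p_adj[sel] <- bh_adjust(res$p[sel])
    }
  }
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (`q_i = min_{j >= i} m p_(j) / j`, capped
#' at 1, returned in input order).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Feature-by-population correlation matrix
#'
#' The Pearson correlations underlying the association heatmap, one row per
#' feature (ordered by family: shape, first-order, kinetic, texture) and
#' one column per population.
#'
#' @inheritParams univariate_scan
#' @return Numeric features x 10 matrix with a `family` attribute giving
#'   each row's feature family.
#' @export
correlation_matrix <- function(features, abundance) {
  scan <- univariate_scan(features, abundance)
  feats <- unique(scan$feature)
  pops <- unique(scan$population)
  m <- matrix(NA_real_, length(feats), length(pops),
              dimnames = list(feats, pops))
  m[cbind(match(scan$feature, feats), match(scan$population, pops))] <- scan$r
  fam <- feature_family(feats)
  ord <- order(factor(fam, levels = c("shape", "first_order", "kinetic",
                                      "texture")))
  m <- m[ord, , drop = FALSE]
  attr(m, "family") <- fam[ord]
  m
}

#' Welch two-sided t-test of a feature between high and low groups
#'
#' @param values Numeric feature values.
#' @param labels Character/factor vector of `"high"`/`"low"` per sample.
#' @return List with `t`, `p`.
#' @export
group_ttest <- function(values, labels) {
  labels <- as.character(labels)
  g <- split(values, labels)
  if (length(g) < 2L)
    stop("labels are single-class ('", names(g), "'): t-test undefined")
  if (any(lengths(g) < 2L)) stop("both groups need >= 2 samples")
  if (stats::var(g[[1]]) == 0 && stats::var(g[[2]]) == 0) {
    dm <- mean(g[["high"]]) - mean(g[["low"]])
    if (dm == 0) return(list(t = 0, p = 1))
    return(list(t = sign(dm) * Inf, p = 0))   # constant but shifted groups
  }
  ht <- stats::t.test(g[["high"]], g[["low"]], var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' High/low t-tests for selected features across all populations
#'
#' Runs [group_ttest()] for each given feature against every population's
#' high/low labels and BH-adjusts the 10 p-values within each feature
#' (the paper-style contrast uses tumor volume and mean PE).
#'
#' @param features Lesions x features matrix.
#' @param abundance A stratified `abundance_table`.
#' @param which_features Feature names to test (default tumor volume and
#'   mean peak enhancement).
#' @return Data frame with `feature`, `population`, `t`, `p`, `p_adj`.
#' @export
feature_group_ttests <- function(features, abundance,
                                 which_features = c("shape_voxel_volume",
                                                    "kin_agg_pe_mean")) {
  stopifnot(!is.null(abundance$labels))
  common <- intersect(rownames(features), rownames(abundance$labels))
  out <- list()
  for (f in which_features) {
    rows <- lapply(colnames(abundance$labels), function(pop) {
      tt <- group_ttest(features[common, f], abundance$labels[common, pop])
      data.frame(feature = f, population = pop, t = tt$t, p = tt$p)
    })
    df <- do.call(rbind, rows)
    df$p_adj <- bh_adjust(df$p)
    out[[f]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
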