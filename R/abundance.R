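#' Score cell-population abundance from expression
#'
#' Marker-based abundance scoring in the MCP-counter style: the score of a
#' population in a sample is the arithmetic mean of `log2(1 + count)` over
#' the population's marker genes present in the matrix. Scores are
#' comparable across samples within a population (not across populations).
#'
#' @param expr Non-negative genes x samples matrix with unique row (gene)
#'   and column (sample) names.
#' @param markers Named list population -> marker gene IDs covering the 10
#'   populations (default: the synthetic marker sets). Markers absent from
#'   the matrix are dropped with a warning; a population with no matching
#'   marker is an error.
#' @return An `abundance_table`: list with `scores` (samples x 10 matrix),
#'   `labels` and `thresholds` (NULL until [stratify_median()]).
#' @export
score_abundance <- function(expr, markers = default_marker_sets()) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("`expr` needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr)))
    stop("gene and sample IDs must be unique")
  if (any(expr < 0)) stop("`expr` must be non-negative")
  pops <- cell_populations()
  if (!all(pops %in% names(markers)))
    stop("`markers` must cover all 10 populations; missing: ",
         paste(setdiff(pops, names(markers)), collapse = ", "))
  lg <- log2(1 + expr)
  scores <- vapply(pops, function(p) {
    found <- intersect(markers[[p]], rownames(expr))
    if (!length(found))
      stop("population '", p, "' has no marker present in the matrix")
    if (length(found) < length(markers[[p]]))
      warning("population '", p, "': ",
              length(markers[[p]]) - length(found), " marker(s) missing")
    colMeans(lg[found, , drop = FALSE])
  }, numeric(ncol(expr)))
  scores <- matrix(scores, ncol = length(pops),
                   dimnames = list(colnames(expr), pops))
  structure(list(scores = scores, labels = NULL, thresholds = NULL),
            class = "abundance_table")
}

#' Median high/low stratification
#'
#' Labels each sample "high" for a population iff its abundance score is
#' greater than or equal to the median score of that population over the
#' samples being labelled, otherwise "low".
#'
#' @param table An `abundance_table` from [score_abundance()].
#' @return The table with `labels` (samples x 10 character matrix) and
#'   `thresholds` (named per-population medians) filled in.
#' @export
stratify_median <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table$scores) < 2L) stop("need >= 2 samples to stratify")
  thr <- apply(table$scores, 2, stats::median)
  labels <- ifelse(sweep(table$scores, 2, thr, `>=`), "high", "low")
  degenerate <- colSums(labels == "high") == nrow(labels)
  if (any(degenerate))
    message("all-'high' population(s) (constant scores): ",
            paste(colnames(labels)[degenerate], collapse = ", "))
  table$labels <- labels
  table$thresholds <- thr
  table
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$scores), " samples x ",
      ncol(x$scores), " populations",
      if (!is.null(x$labels)) "; stratified" else "", "\n", sep = "")
  invisible(x)
}

#' Read / write marker tables
#'
#' Markers are stored as a two-column TSV (population, gene).
#'
#' @param path TSV path.
#' @return `read_markers()`: named list population -> gene IDs.
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("population", "gene") %in% names(df)))
    stop("marker table needs columns 'population' and 'gene'")
  split(df$gene, factor(df$population, levels = unique(df$population)))
}

#' @rdname read_markers
#' @param markers Named list population -> gene IDs.
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(population = rep(names(markers), lengths(markers)),
                   gene = unlist(markers, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
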