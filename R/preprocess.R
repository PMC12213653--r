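#' Z-score normalize each gene across all samples
#'
#' Centers every gene row to mean 0 and scales to sample standard
#' deviation 1 (n-1 denominator), pooling all conditions and time points.
#' Zero-variance genes cannot be scaled and are mapped to all-zero rows
#' with a warning.
#'
#' @param x A `gt_expression` object with at least two samples.
#' @return The normalized `gt_expression` (`normalized` flag set).
#' @export
zscore_normalize <- function(x) {
  stopifnot(inherits(x, "gt_expression"))
  if (ncol(x$values) < 2)
    stop("Z-score normalization needs at least two samples")
  mu <- rowMeans(x$values)
  sdv <- apply(x$values, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) mapped to all-zero rows: ",
            paste(utils::head(rownames(x$values)[flat], 5), collapse = ", "))
    sdv[flat] <- 1
  }
  vals <- (x$values - mu) / sdv
  vals[flat, ] <- 0
  expression_matrix(vals, x$samples, normalized = TRUE)
}

#' Select the most variably expressed genes
#'
#' Ranks genes by descending per-gene sample variance across all samples
#' (raw, un-normalized values: per-gene Z-scoring would equalize all
#' variances) and keeps the top `n`. Ties are broken by gene identifier,
#' lexicographically in the C locale, so the ranking is deterministic.
#'
#' @param x A `gt_expression` object.
#' @param n Number of genes to keep (default 1000).
#' @return A `gt_selection` list with `ranked_genes`, `variances`, and
#'   `selected` (the top `n` in rank order).
#' @export
select_top_variance <- function(x, n = 1000) {
  stopifnot(inherits(x, "gt_expression"))
  if (n <= 0) stop("`n` must be a positive integer")
  if (x$normalized)
    warning("selecting by variance on Z-scored values; per-gene variances ",
            "are all ~1 and the ranking is driven by ties")
  v <- apply(x$values, 1, stats::var)
  ids <- rownames(x$values)
  ord <- order(-v, ids, method = "radix")
  ranked <- ids[ord]
  if (n > length(ranked)) {
    warning("requested ", n, " genes but only ", length(ranked),
            " available; returning all")
    n <- length(ranked)
  }
  structure(
    list(ranked_genes = ranked, variances = v[ord],
         selected = ranked[seq_len(n)], n_requested = n),
    class = "gt_selection"
  )
}

#' Retain genes co-expressed with at least one other gene
#'
#' Computes all pairwise Pearson correlations among the given genes
#' across every sample (all conditions and time points pooled) and keeps
#' each gene whose maximum signed correlation with any other listed gene
#' meets the threshold. Signed r is used, not |r|: the filter selects
#' co-expressed genes, and anti-correlated partners do not count.
#' Constant genes, whose correlation is undefined, are dropped with a
#' warning.
#'
#' @param x A `gt_expression` object with at least three samples.
#' @param genes Character vector of gene identifiers to filter.
#' @param threshold_r Retention threshold on signed Pearson r
#'   (default 0.5); the comparison is inclusive (`>=`).
#' @return Character vector of retained genes, in input order.
#' @export
correlation_filter <- function(x, genes, threshold_r = 0.5) {
  stopifnot(inherits(x, "gt_expression"))
  if (threshold_r < -1 || threshold_r > 1)
    stop("`threshold_r` must lie in [-1, 1]")
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing) > 0)
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(genes) < 2)
    stop("correlation filter needs at least two genes")
  if (ncol(x$values) < 3)
    stop("correlation filter needs at least three samples")
  m <- x$values[genes, , drop = FALSE]
  sdv <- apply(m, 1, stats::sd)
  const <- sdv == 0
  if (any(const))
    warning("dropping constant gene(s) with undefined correlation: ",
            paste(genes[const], collapse = ", "))
  m <- m[!const, , drop = FALSE]
  if (nrow(m) < 2) return(character(0))
  r <- stats::cor(t(m))
  diag(r) <- -Inf
  keep <- apply(r, 1, max) >= threshold_r
  genes[genes %in% rownames(m)[keep]]
}
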