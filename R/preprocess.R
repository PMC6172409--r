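#' Remove the lowest-mean genes of a layer
#'
#' Drops the `floor(fraction * n_genes)` genes with the smallest arithmetic
#' mean across samples (computed on the linear scale, as provided). Ties
#' are broken by input order: among equal means, earlier genes are kept.
#'
#' @param m an [expr_matrix()] (or matrix with dimnames).
#' @param fraction proportion of genes to remove, in `[0, 1)`.
#' @return the filtered matrix, sample set unchanged.
#' @export
filter_low_mean <- function(m, fraction = 0.25) {
  if (nrow(m) == 0L) stop("empty expression matrix")
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_drop <- floor(fraction * nrow(m))
  if (n_drop == 0) return(m)
  means <- rowMeans(m)
  # rank genes by descending mean, earlier index wins ties; keep the top block
  ord <- order(-means, seq_along(means))
  keep <- sort(ord[seq_len(nrow(m) - n_drop)])
  m[keep, , drop = FALSE]
}

#' Median absolute deviation per gene on log2(x + 1)
#'
#' No scale constant is applied (it cannot change a top-N ranking).
#'
#' @param m expression matrix, linear scale.
#' @return numeric vector of per-gene MADs.
#' @export
gene_mad <- function(m) {
  x <- log2(as_plain_matrix(m) + 1)
  apply(x, 1, function(v) median(abs(v - median(v))))
}

#' Keep the most variable genes of a layer
#'
#' Retains the `n` genes with the largest median absolute deviation of
#' `log2(x + 1)` values. If `n` is at least the current gene count the
#' matrix is returned unchanged. Ties are broken by input order (earlier
#' kept); output preserves input gene order.
#'
#' @param m an [expr_matrix()].
#' @param n number of genes to keep (>= 1).
#' @return the reduced matrix.
#' @export
select_top_mad <- function(m, n) {
  if (n < 1) stop("n must be >= 1")
  if (n >= nrow(m)) return(m)
  mads <- gene_mad(m)
  ord <- order(-mads, seq_along(mads))
  keep <- sort(ord[seq_len(n)])
  m[keep, , drop = FALSE]
}

#' Clustering input transform: median-centered log2(x + 1)
#'
#' Per-gene median centering prevents absolute expression level from
#' dominating the Pearson distance between sample profiles.
#'
#' @param m expression matrix, linear scale.
#' @return plain numeric matrix, genes x samples.
#' @export
cluster_input <- function(m) {
  x <- log2(as_plain_matrix(m) + 1)
  x - apply(x, 1, median)
}

#' Standard per-layer preprocessing for consensus clustering
#'
#' Mean filter, top-MAD selection, then the median-centered log transform,
#' restricted to the requested samples (typically tumors only).
#'
#' @param m an [expr_matrix()].
#' @param samples sample IDs to retain (default: all).
#' @param mean_filter fraction of low-mean genes to drop.
#' @param top_mad number of top-MAD genes to keep (capped at the count
#'   remaining after the mean filter).
#' @return plain matrix ready for [build_consensus()].
#' @export
preprocess_layer <- function(m, samples = colnames(m), mean_filter = 0.25,
                             top_mad = 3000) {
  m <- m[, samples, drop = FALSE]
  m <- filter_low_mean(m, mean_filter)
  m <- select_top_mad(m, min(top_mad, nrow(m)))
  cluster_input(m)
}
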