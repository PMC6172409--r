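#' Pearson distance between sample profiles
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation between the
#' profiles of samples i and j across features; `d` lies in `[0, 2]` with a
#' zero diagonal.
#'
#' @param x numeric matrix, features x samples.
#' @return symmetric n x n distance matrix with sample dimnames.
#' @export
pearson_distance <- function(x) {
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance sample profile(s): ", paste(bad, collapse = ", "))
  }
  d <- 1 - cor(x)
  diag(d) <- 0
  d
}

#' Agglomerative clustering cut at k groups
#'
#' Hierarchical clustering (`stats::hclust`) of a distance matrix with the
#' given linkage, cut into k clusters. Deterministic for a given distance
#' matrix; merge ties follow `hclust`'s smallest-index convention.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @param k number of clusters (1..n).
#' @return integer labels in 1..k, named by sample.
#' @export
hclust_cut <- function(d, linkage = c("complete", "average", "single"), k) {
  linkage <- match.arg(linkage)
  dd <- if (inherits(d, "dist")) d else as.dist(d)
  n <- attr(dd, "Size")
  if (k > n) stop("k exceeds the number of samples")
  if (k == n) {
    labs <- seq_len(n)
    names(labs) <- attr(dd, "Labels")
    return(labs)
  }
  cutree(hclust(dd, method = linkage), k = k)
}

#' Monti-style consensus clustering over subsampled runs
#'
#' For each replicate, a fraction `p_item` of samples is drawn without
#' replacement, clustered with [pearson_distance()] + [hclust_cut()], and
#' the co-clustering / co-sampling tallies are updated for every candidate
#' K (the same subsample serves all K, as in the original procedure). The
#' consensus matrix is `M = co-clustered / co-sampled`, with unit diagonal;
#' pairs never co-sampled get `M = 0` with a warning. Final labels per K
#' come from re-clustering `1 - M`.
#'
#' Randomness contract: one seed; per-replicate subsample draws are
#' consumed in replicate order, so results do not depend on evaluation
#' order elsewhere.
#'
#' @param x numeric matrix, features x samples (e.g. from
#'   [preprocess_layer()]).
#' @param k_range candidate cluster numbers, a contiguous range from 2.
#' @param reps number of subsampled replicates.
#' @param p_item fraction of samples per replicate (0 < p_item <= 1).
#' @param linkage linkage for both the inner and the final clustering.
#' @param seed RNG seed; `NULL` continues the current stream.
#' @param keep_reps store per-replicate subsample indices and labels
#'   (needed for exact recount checks; off by default to save memory).
#' @return object of class `consensus_set`: list with `results` (one
#'   `consensus_result` per K: `K`, consensus matrix `M`, co-sample count
#'   matrix `C`, `labels`, `hc`, optional `rep_labels`), plus the call
#'   parameters and `samples`.
#' @export
build_consensus <- function(x, k_range = 2:6, reps = 50, p_item = 0.8,
                            linkage = "complete", seed = NULL,
                            keep_reps = FALSE) {
  n <- ncol(x)
  stopifnot(reps >= 1, p_item > 0, p_item <= 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > n) stop("k_max exceeds the number of samples")
  n_sub <- ceiling(p_item * n)
  if (max(k_range) > n_sub) stop("k_max exceeds the subsample size")
  if (!is.null(seed)) set.seed(seed)
  samples <- colnames(x)

  C <- matrix(0L, n, n, dimnames = list(samples, samples))
  conn <- lapply(k_range, function(k) C)
  names(conn) <- as.character(k_range)
  rep_store <- if (keep_reps)
    setNames(vector("list", length(k_range)), as.character(k_range)) else NULL

  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, n_sub))
    d <- pearson_distance(x[, idx, drop = FALSE])
    hc <- hclust(as.dist(d), method = linkage)
    C[idx, idx] <- C[idx, idx] + 1L
    for (kc in as.character(k_range)) {
      labs <- cutree(hc, k = as.integer(kc))
      for (members in split(idx, labs))
        conn[[kc]][members, members] <- conn[[kc]][members, members] + 1L
      if (keep_reps) {
        names(labs) <- samples[idx]
        rep_store[[kc]][[r]] <- labs
      }
    }
  }

  never <- C == 0 & upper.tri(C)
  if (any(never))
    warning(sum(never), " sample pair(s) never co-sampled; consensus set to 0")

  results <- lapply(as.character(k_range), function(kc) {
    M <- matrix(0, n, n, dimnames = list(samples, samples))
    pos <- C > 0
    M[pos] <- conn[[kc]][pos] / C[pos]
    diag(M) <- 1
    hc <- hclust(as.dist(1 - M), method = linkage)
    labels <- cutree(hc, k = as.integer(kc))
    structure(list(K = as.integer(kc), M = M, C = C, labels = labels,
                   hc = hc, rep_labels = rep_store[[kc]]),
              class = "consensus_result")
  })
  names(results) <- as.character(k_range)
  structure(list(results = results, k_range = k_range, reps = reps,
                 p_item = p_item, linkage = linkage, samples = samples),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> n=%d samples, K=%s, reps=%d, p_item=%g\n",
              length(x$samples), paste(range(x$k_range), collapse = ".."),
              x$reps, x$p_item))
  invisible(x)
}

#' Final cluster labels from a consensus matrix
#'
#' Re-clusters `1 - M` with the stored linkage and cuts at the result's K.
#'
#' @param res a `consensus_result` (one element of
#'   `build_consensus()$results`).
#' @param linkage linkage for the final clustering.
#' @return integer labels named by sample.
#' @export
final_clusters <- function(res, linkage = "complete") {
  hclust_cut(1 - res$M, linkage = linkage, k = res$K)
}
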