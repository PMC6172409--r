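#' Binary cluster-of-clusters encoding
#'
#' Each sample becomes a binary vector of length `sum(K_i)` over the `t`
#' input labelings: block i holds `K_i` indicator columns, with a single 1
#' at the sample's cluster in labeling i. Row sums therefore all equal `t`.
#'
#' @param label_sets named list of per-dataset label vectors (each named by
#'   sample, covering the same samples).
#' @return binary matrix, samples x sum(K_i), column names
#'   `<dataset>.k<cluster>`.
#' @export
encode_coc <- function(label_sets) {
  stopifnot(length(label_sets) >= 1)
  if (is.null(names(label_sets)))
    names(label_sets) <- paste0("ds", seq_along(label_sets))
  samples <- names(label_sets[[1]])
  if (is.null(samples)) stop("labelings must be named by sample")
  for (ls in label_sets) {
    if (is.null(names(ls)) || !setequal(names(ls), samples))
      stop("labelings cover different sample sets")
  }
  blocks <- lapply(names(label_sets), function(nm) {
    labs <- label_sets[[nm]][samples]
    ks <- sort(unique(labs))
    b <- vapply(ks, function(k) as.integer(labs == k),
                integer(length(samples)))
    colnames(b) <- paste0(nm, ".k", ks)
    b
  })
  enc <- do.call(cbind, blocks)
  rownames(enc) <- samples
  enc
}

lower_tri_entries <- function(M) M[lower.tri(M)]

#' Consensus CDF, area under it, and relative change in area
#'
#' The empirical CDF is taken over the `n(n-1)/2` strictly-lower-triangular
#' consensus entries. `A(K)` is the exact area under that step CDF on
#' `[0, 1]`; `Delta(2) = A(2)` and
#' `Delta(K+1) = (A(K+1) - A(K)) / A(K)`.
#'
#' @param results the `results` list of a [build_consensus()] object
#'   (contiguous K from 2).
#' @return list with `cdf` (one ecdf per K), `A` and `delta` (named by K).
#' @export
cdf_area_delta <- function(results) {
  ks <- as.integer(names(results))
  if (ks[1] != 2 || any(diff(ks) != 1))
    stop("K range must be contiguous from 2")
  A <- vapply(results, function(res) {
    v <- lower_tri_entries(res$M)
    xs <- sort(unique(v))
    Fx <- vapply(xs, function(u) mean(v <= u), numeric(1))
    sum(Fx * (c(xs[-1], 1) - xs))
  }, numeric(1))
  delta <- A
  if (length(A) > 1)
    delta[-1] <- diff(A) / A[-length(A)]
  if (length(A) == 1)
    message("single K supplied; delta defined only at K = 2")
  cdf <- lapply(results, function(res) stats::ecdf(lower_tri_entries(res$M)))
  list(cdf = cdf, A = A, delta = delta)
}

#' Proportion of ambiguous clustering
#'
#' `PAC = CDF(u2) - CDF(u1)` over the lower-triangular consensus entries:
#' the fraction of sample pairs with ambiguous (intermediate) consensus.
#' Lower is cleaner.
#'
#' @param res a `consensus_result`.
#' @param u1,u2 ambiguity window, `0 <= u1 < u2 <= 1`.
#' @return PAC in `[0, 1]`.
#' @export
pac <- function(res, u1 = 0.1, u2 = 0.9) {
  stopifnot(u1 >= 0, u1 < u2, u2 <= 1)
  v <- lower_tri_entries(res$M)
  mean(v <= u2) - mean(v <= u1)
}

#' Average silhouette width
#'
#' `s(i) = (b - a) / max(a, b)` with `a` the mean within-cluster distance
#' (excluding self) and `b` the smallest mean distance to another cluster.
#' Singletons score 0; so does the degenerate `a = b = 0` case.
#'
#' @param labels cluster labels (>= 2 clusters present).
#' @param d distance matrix over the same samples.
#' @return mean silhouette over samples, in `[-1, 1]`.
#' @export
asw <- function(labels, d) {
  d <- as.matrix(d)
  n <- length(labels)
  stopifnot(nrow(d) == n)
  if (length(unique(labels)) < 2)
    stop("silhouette undefined with a single cluster")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) next  # singleton: s = 0
    a <- mean(d[i, own][-match(i, which(own))])
    b <- min(tapply(d[i, !own], labels[!own], mean))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' merge-height (cophenetic) distances implied by a dendrogram built from
#' them.
#'
#' @param d distance matrix (or `dist`) the dendrogram was built from.
#' @param hc an `hclust` object.
#' @return CPCC in `[-1, 1]`, or `NA` with a warning when the distance
#'   vector is constant.
#' @export
cpcc <- function(d, hc) {
  dd <- if (inherits(d, "dist")) d else as.dist(d)
  coph <- cophenetic(hc)
  if (var(as.vector(dd)) == 0 || var(as.vector(coph)) == 0) {
    warning("constant distance vector; CPCC undefined")
    return(NA_real_)
  }
  cor(as.vector(dd), as.vector(coph))
}

#' Per-K selection metrics for a consensus run
#'
#' Computes, for every K of a [build_consensus()] result: the consensus-CDF
#' area `A(K)` and its relative change `Delta(K)`, `PAC(K)`, the average
#' silhouette width of the final labels against a base distance, and the
#' cophenetic correlation between the base distance and each K's final
#' consensus dendrogram (how faithfully the per-K consensus tree
#' represents the observed distances; correlating the tree against its own
#' `1 - M` instead would sit near 1 for every K and carry no information).
#'
#' @param cc a `consensus_set`.
#' @param d_base distance matrix over the same samples used for the
#'   silhouette (typically the Pearson distance of the clustering input).
#' @param u1,u2 PAC window.
#' @return data.frame with columns `K`, `A`, `delta`, `PAC`, `ASW`, `CPCC`.
#' @export
kselect_metrics <- function(cc, d_base, u1 = 0.1, u2 = 0.9) {
  cad <- cdf_area_delta(cc$results)
  rows <- lapply(cc$results, function(res) {
    data.frame(K = res$K,
               A = cad$A[[as.character(res$K)]],
               delta = cad$delta[[as.character(res$K)]],
               PAC = pac(res, u1, u2),
               ASW = asw(res$labels, d_base),
               CPCC = cpcc(d_base, res$hc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the cluster number by a four-metric vote
#'
#' Each metric casts one vote: ASW and CPCC vote their argmax, PAC its
#' argmin, and Delta(K) the largest K whose relative area change is at
#' least `delta_elbow` (the declared elbow rule; if no K qualifies the
#' smallest K is voted). The selected K is the majority vote; ties go to
#' the smallest voted K.
#'
#' @param metrics a [kselect_metrics()] data.frame.
#' @param delta_elbow elbow threshold on Delta(K).
#' @return list with `selected` (integer K) and `votes` (named integer
#'   vector, one per metric).
#' @export
select_k <- function(metrics, delta_elbow = 0.1) {
  K <- metrics$K
  v_asw <- K[which.max(metrics$ASW)]
  v_cpcc <- if (all(is.na(metrics$CPCC))) min(K) else
    K[which.max(metrics$CPCC)]
  v_pac <- K[which.min(metrics$PAC)]
  eligible <- K[!is.na(metrics$delta) & metrics$delta >= delta_elbow]
  v_delta <- if (length(eligible)) max(eligible) else min(K)
  votes <- c(ASW = v_asw, CPCC = v_cpcc, delta = v_delta, PAC = v_pac)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(selected = min(winners), votes = votes)
}

#' Full subtype discovery: per-layer consensus, CoC integration, K vote
#'
#' Runs consensus clustering on each preprocessed layer, picks each
#' layer's own K by the four-metric vote, encodes the per-layer labels as
#' a binary cluster-of-clusters matrix, consensus-clusters that encoding,
#' and selects the final K.
#'
#' @param inputs named list of preprocessed matrices (features x samples,
#'   shared samples), e.g. from [preprocess_layer()].
#' @param k_max largest K evaluated (candidates 2..k_max).
#' @param reps,p_item,linkage consensus-clustering parameters.
#' @param seed master seed; per-layer and CoC runs use derived seeds.
#' @param delta_elbow,u1,u2 K-selection parameters.
#' @return list: `layer_cc`, `layer_metrics`, `layer_k` (named integer),
#'   `encoding`, `coc_cc`, `coc_metrics`, `selection` (votes), `selected_k`
#'   and `labels` (final subtype labels at the selected K).
#' @export
discover_subtypes <- function(inputs, k_max = 6, reps = 50, p_item = 0.8,
                              linkage = "complete", seed = 1L,
                              delta_elbow = 0.1, u1 = 0.1, u2 = 0.9) {
  stopifnot(k_max >= 2)
  layer_cc <- list(); layer_metrics <- list(); layer_k <- integer(0)
  labelings <- list()
  for (i in seq_along(inputs)) {
    nm <- names(inputs)[i]
    x <- inputs[[i]]
    cc <- build_consensus(x, k_range = 2:k_max, reps = reps, p_item = p_item,
                          linkage = linkage, seed = seed + i * 1009L)
    met <- kselect_metrics(cc, pearson_distance(x), u1 = u1, u2 = u2)
    k_i <- select_k(met, delta_elbow)$selected
    layer_cc[[nm]] <- cc
    layer_metrics[[nm]] <- met
    layer_k[nm] <- k_i
    labelings[[nm]] <- cc$results[[as.character(k_i)]]$labels
  }
  enc <- encode_coc(labelings)
  coc_cc <- build_consensus(t(enc), k_range = 2:k_max, reps = reps,
                            p_item = p_item, linkage = linkage,
                            seed = seed + 104729L)
  coc_metrics <- kselect_metrics(coc_cc, pearson_distance(t(enc)),
                                 u1 = u1, u2 = u2)
  selection <- select_k(coc_metrics, delta_elbow)
  k_sel <- selection$selected
  list(layer_cc = layer_cc, layer_metrics = layer_metrics, layer_k = layer_k,
       encoding = enc, coc_cc = coc_cc, coc_metrics = coc_metrics,
       selection = selection, selected_k = k_sel,
       labels = coc_cc$results[[as.character(k_sel)]]$labels)
}
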