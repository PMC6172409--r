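#' Signal-to-noise ranking of genes between two groups
#'
#' `s2n = (mu1 - mu2) / (sigma1 + sigma2)` per gene, with each standard
#' deviation floored at `0.2 * |mu|` of its group (0.2 when the mean is
#' zero), the canonical convention that keeps low-variance genes from
#' dominating. Genes are sorted by descending score; ties break
#' lexicographically by gene ID.
#'
#' @param m expression matrix, genes x samples (supply log-scale values if
#'   a log-scale metric is wanted).
#' @param groups two-level factor; the score is level1 minus level2, so
#'   positive scores mark genes high in the first level.
#' @param sd_floor_frac,sd_floor_zero floor constants.
#' @return data.frame of class `ranked_list`: `gene`, `score`, ordered.
#' @export
signal_to_noise <- function(m, groups, sd_floor_frac = 0.2,
                            sd_floor_zero = 0.2) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 3))
    stop("signal-to-noise needs >= 3 samples per group")
  x <- as_plain_matrix(m)
  g1 <- groups == levels(groups)[1]
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, !g1, drop = FALSE])
  s1 <- apply(x[, g1, drop = FALSE], 1, sd)
  s2 <- apply(x[, !g1, drop = FALSE], 1, sd)
  floor1 <- ifelse(m1 == 0, sd_floor_zero, sd_floor_frac * abs(m1))
  floor2 <- ifelse(m2 == 0, sd_floor_zero, sd_floor_frac * abs(m2))
  s1 <- pmax(s1, floor1); s2 <- pmax(s2, floor2)
  score <- (m1 - m2) / (s1 + s2)
  ord <- order(-score, rownames(x))
  structure(data.frame(gene = rownames(x)[ord], score = score[ord],
                       row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: genes in the set add `|score|^weight / N_R`
#' (`N_R` = sum of `|score|^weight` over in-set genes); genes outside
#' subtract `1 / (N - N_H)`. The enrichment score is the running-sum value
#' of maximal absolute deviation from zero (signed).
#'
#' @param rl a [signal_to_noise()] ranked list (or data.frame with `gene`,
#'   `score` ordered by descending score).
#' @param gene_set character vector of gene IDs.
#' @param weight exponent on the hit increments (1 = the standard
#'   "weighted" statistic).
#' @return list: `ES` and the `running` sum vector.
#' @export
enrichment_score <- function(rl, gene_set, weight = 1) {
  hit <- rl$gene %in% gene_set
  if (!any(hit)) stop("gene set has no overlap with the ranked list")
  N <- nrow(rl); N_H <- sum(hit)
  w <- abs(rl$score)^weight
  N_R <- sum(w[hit])
  inc <- numeric(N)
  if (N_R > 0) inc[hit] <- w[hit] / N_R else inc[hit] <- 1 / N_H
  if (N > N_H) inc[!hit] <- -1 / (N - N_H)
  running <- cumsum(inc)
  ES <- running[which.max(abs(running))]
  list(ES = ES, running = running)
}

# null ES values for a given set size, drawn from the ranked universe
null_es <- function(rl, size, n_perm, weight) {
  vapply(seq_len(n_perm), function(i) {
    enrichment_score(rl, sample(rl$gene, size), weight)$ES
  }, numeric(1))
}

#' Gene-set enrichment analysis with gene-set permutation
#'
#' Ranks genes by [signal_to_noise()], computes the weighted enrichment
#' score per set, and builds each set's null from `n_perm` random same-size
#' gene sets drawn from the ranked universe (the "gene_set" permutation
#' type). `NES = ES / mean(|null ES| of matching sign)`; the nominal p is
#' the fraction of same-sign null ES at least as extreme; the FDR q uses
#' the standard ratio of null-NES to observed-NES tail fractions on the
#' pooled signed null.
#'
#' @param m expression matrix, genes x samples.
#' @param groups two-level factor (level1 - level2 scores).
#' @param gene_sets named list of gene ID vectors (e.g. [read_gmt()]).
#' @param n_perm permutations per set; 0 skips inference (p and q `NA`).
#' @param weight ES weight exponent.
#' @param min_size,max_size set-size filter after intersection with the
#'   measured universe.
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return data.frame of class `gsea_result`: `set`, `size`, `ES`, `NES`,
#'   `p`, `q`, ordered by NES.
#' @export
run_gsea <- function(m, groups, gene_sets, n_perm = 1000, weight = 1,
                     min_size = 15, max_size = 500, seed = NULL) {
  rl <- signal_to_noise(m, groups)
  run_gsea_ranked(rl, gene_sets, n_perm = n_perm, weight = weight,
                  min_size = min_size, max_size = max_size, seed = seed)
}

#' @rdname run_gsea
#' @param rl a precomputed ranked list.
#' @export
run_gsea_ranked <- function(rl, gene_sets, n_perm = 1000, weight = 1,
                            min_size = 15, max_size = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  universe <- rl$gene
  sets <- lapply(gene_sets, intersect, universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  dropped <- names(sets)[!keep & sizes == 0]
  if (length(dropped))
    message(length(dropped), " set(s) skipped: no overlap with universe")
  sets <- sets[keep]; sizes <- sizes[keep]
  if (length(sets) == 0) stop("no gene sets pass the size filter")

  ES <- vapply(sets, function(s) enrichment_score(rl, s, weight)$ES,
               numeric(1))

  if (n_perm == 0) {
    out <- data.frame(set = names(sets), size = sizes, ES = ES,
                      NES = NA_real_, p = NA_real_, q = NA_real_,
                      row.names = NULL)
    return(structure(out[order(-out$ES), ], class = c("gsea_result",
                                                      "data.frame")))
  }

  NES <- numeric(length(sets)); p <- numeric(length(sets))
  null_nes_pool <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nulls <- null_es(rl, sizes[i], n_perm, weight)
    pos <- nulls[nulls >= 0]; neg <- nulls[nulls < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    same <- if (ES[i] >= 0) pos else neg
    denom <- if (ES[i] >= 0) mean_pos else mean_neg
    NES[i] <- if (is.na(denom) || denom == 0) NA_real_ else ES[i] / denom
    p[i] <- if (length(same) == 0) NA_real_ else
      mean(abs(same) >= abs(ES[i]))
    # normalize the whole null by the sign-matched means for the FDR pool
    nn <- nulls
    nn[nulls >= 0] <- if (is.na(mean_pos) || mean_pos == 0) NA else
      nulls[nulls >= 0] / mean_pos
    nn[nulls < 0] <- if (is.na(mean_neg) || mean_neg == 0) NA else
      nulls[nulls < 0] / mean_neg
    null_nes_pool[[i]] <- nn[!is.na(nn)]
  }
  pool <- unlist(null_nes_pool)
  q <- vapply(seq_along(sets), function(i) {
    if (is.na(NES[i])) return(NA_real_)
    if (NES[i] >= 0) {
      null_tail <- if (any(pool >= 0)) mean(pool[pool >= 0] >= NES[i]) else NA
      obs_tail <- mean(NES[NES >= 0] >= NES[i])
    } else {
      null_tail <- if (any(pool < 0)) mean(pool[pool < 0] <= NES[i]) else NA
      obs_tail <- mean(NES[NES < 0] <= NES[i])
    }
    if (is.na(null_tail) || obs_tail == 0) return(NA_real_)
    min(1, null_tail / obs_tail)
  }, numeric(1))

  out <- data.frame(set = names(sets), size = sizes, ES = ES, NES = NES,
                    p = p, q = q, row.names = NULL)
  structure(out[order(-out$NES), ], class = c("gsea_result", "data.frame"))
}

#' Over-representation analysis over user-supplied gene sets
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' list and each set, within a stated universe, with BH correction across
#' sets.
#'
#' @param query gene IDs of interest (must be a subset of `universe`).
#' @param universe background gene IDs.
#' @param gene_sets named list of gene ID vectors.
#' @return data.frame: `set`, `size` (in universe), `overlap`, `p`, `q`,
#'   ordered by p.
#' @export
ora_enrich <- function(query, universe, gene_sets) {
  if (length(query) == 0) stop("query gene list is empty")
  if (!all(query %in% universe)) stop("query must be a subset of universe")
  universe <- unique(universe); query <- unique(query)
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- phyper(k - 1, length(s), N - length(s), nq, lower.tail = FALSE)
    data.frame(set = nm, size = length(s), overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
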