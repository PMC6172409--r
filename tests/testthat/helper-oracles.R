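# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (loops, enumeration) so they
# stay independent of the package's vectorized implementations.

# step-up BH from the definition: q_(i) = min_{j>=i} m p_(j) / j
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# AUC by explicit positive/negative pair counting, ties worth 1/2
auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  wins <- 0
  for (a in sp) for (b in sn)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(sp) * length(sn))
}

# consensus matrix recounted from stored per-replicate labels
consensus_recount <- function(res, samples) {
  n <- length(samples)
  cocluster <- matrix(0, n, n, dimnames = list(samples, samples))
  cosample <- matrix(0, n, n, dimnames = list(samples, samples))
  for (labs in res$rep_labels) {
    ids <- names(labs)
    for (a in ids) for (b in ids) {
      cosample[a, b] <- cosample[a, b] + 1
      if (labs[a] == labs[b]) cocluster[a, b] <- cocluster[a, b] + 1
    }
  }
  M <- matrix(0, n, n, dimnames = list(samples, samples))
  M[cosample > 0] <- cocluster[cosample > 0] / cosample[cosample > 0]
  diag(M) <- 1
  M
}

# exhaustive triple loop over candidate (miRNA, lncRNA, mRNA) combinations
triplets_bruteforce <- function(lnc_mrna, mir_lnc, mir_mrna) {
  key <- function(a, b) paste(a, b, sep = "|")
  lm_keys <- key(lnc_mrna$gene_a, lnc_mrna$gene_b)
  ml_keys <- key(mir_lnc$gene_a, mir_lnc$gene_b)
  mm_keys <- key(mir_mrna$gene_a, mir_mrna$gene_b)
  mirs <- unique(c(mir_lnc$gene_a, mir_mrna$gene_a))
  lncs <- unique(c(lnc_mrna$gene_a, mir_lnc$gene_b))
  mrnas <- unique(c(lnc_mrna$gene_b, mir_mrna$gene_b))
  out <- character(0)
  for (mu in mirs) for (L in lncs) for (M in mrnas) {
    if (key(L, M) %in% lm_keys && key(mu, L) %in% ml_keys &&
        key(mu, M) %in% mm_keys)
      out <- c(out, paste(mu, L, M))
  }
  sort(out)
}

# hypergeometric upper tail by direct summation
hyper_tail <- function(overlap, set_size, universe, query) {
  k_max <- min(set_size, query)
  if (overlap > k_max) return(0)
  sum(vapply(overlap:k_max, function(k) {
    choose(set_size, k) * choose(universe - set_size, query - k) /
      choose(universe, query)
  }, numeric(1)))
}

# a consensus_result-like object with a prescribed lower-tri entry set
fake_res <- function(entries, K = 2) {
  n_pairs <- length(entries)
  n <- (1 + sqrt(1 + 8 * n_pairs)) / 2
  stopifnot(n == round(n))
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- entries
  M <- M + t(M)
  diag(M) <- 1
  list(K = K, M = M)
}

# symmetric 0/1 consensus entries with an exact fraction z of zeros
binary_entries <- function(n, z) {
  n_pairs <- n * (n - 1) / 2
  k <- round(z * n_pairs)
  stopifnot(k == z * n_pairs)
  c(rep(0, k), rep(1, n_pairs - k))
}

# small default simulation for fast module tests
tiny_cfg <- function(...) {
  args <- list(n_tumor = 40, n_normal = 10,
               n_genes = c(mrna = 60, mirna = 30, lncrna = 40),
               n_triplets = 4, seed = 42L)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(sim_config, args)
}

# a vector pair with an exact sample Pearson correlation r (Gram-Schmidt)
exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  x <- as.vector(scale(x))
  e <- as.vector(scale(e))
  y <- r * x + sqrt(1 - r^2) * e
  list(x = x, y = y)
}
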