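#' Per-gene two-group F test
#'
#' One-way ANOVA on `log2(x + 1)` values per gene:
#' `F = MS_between / MS_within` with df `(1, n - 2)`. For two groups this
#' equals the squared equal-variance t statistic. Genes with zero
#' within-group variance and zero between-group difference get `F = 0`,
#' `p = 1`; zero within-group variance with a nonzero difference gives
#' `F = Inf`, `p = 0`.
#'
#' @param m expression matrix (linear scale), genes x samples.
#' @param groups two-level factor (or coercible), one entry per sample,
#'   both levels with >= 2 samples.
#' @return data.frame: `gene`, `F`, `p`.
#' @export
two_group_f_test <- function(m, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  x <- log2(as_plain_matrix(m) + 1)
  x1 <- x[, groups == levels(groups)[1], drop = FALSE]
  x2 <- x[, groups == levels(groups)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df2 <- n1 + n2 - 2
  Fs <- ifelse(ssw > 0, ssb / (ssw / df2), ifelse(ssb > 0, Inf, 0))
  p <- ifelse(is.infinite(Fs), 0, pf(Fs, 1, df2, lower.tail = FALSE))
  p[Fs == 0 & ssw == 0] <- 1
  data.frame(gene = rownames(m), F = Fs, p = p, row.names = NULL)
}

#' Per-gene log2 fold change with pseudocount
#'
#' `log2((mean_tumor + 1) / (mean_normal + 1))` on linear-scale values.
#' The pseudocount guards against zero means in FPKM-like data.
#'
#' @param m expression matrix (linear scale).
#' @param groups two-level factor; the first level is the reference
#'   (denominator) group.
#' @return named numeric vector of fold changes.
#' @export
log2_fold_change <- function(m, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  x <- as_plain_matrix(m)
  ref <- rowMeans(x[, groups == levels(groups)[1], drop = FALSE])
  alt <- rowMeans(x[, groups == levels(groups)[2], drop = FALSE])
  setNames(log2((alt + 1) / (ref + 1)), rownames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped
#' at 1, mapped back to input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Tumor-vs-normal differential expression table
#'
#' Combines the F test, fold change and BH adjustment into the standard
#' calling table.
#'
#' @param m expression matrix (linear scale).
#' @param groups two-level factor; first level = reference (normal).
#' @param fdr,lfc_abs calling thresholds (strict: `q < fdr`,
#'   `|lfc| > lfc_abs`).
#' @return data.frame of class `de_table`: `gene`, `F`, `p`, `q`, `lfc`,
#'   `call` in `{up, down, none}`.
#' @export
run_diffexpr <- function(m, groups, fdr = 0.05, lfc_abs = 0.57) {
  ft <- two_group_f_test(m, groups)
  ft$q <- bh_adjust(ft$p)
  ft$lfc <- unname(log2_fold_change(m, groups))
  ft$call <- call_degs(ft, fdr = fdr, lfc_abs = lfc_abs)
  class(ft) <- c("de_table", "data.frame")
  ft
}

#' Call differentially expressed genes
#'
#' Strict thresholds as conventionally printed: up when `q < fdr` and
#' `lfc > lfc_abs`; down when `q < fdr` and `lfc < -lfc_abs`; otherwise
#' none.
#'
#' @param de data.frame with columns `q` and `lfc`.
#' @param fdr,lfc_abs thresholds.
#' @return character vector of calls.
#' @export
call_degs <- function(de, fdr = 0.05, lfc_abs = 0.57) {
  ifelse(de$q < fdr & de$lfc > lfc_abs, "up",
         ifelse(de$q < fdr & de$lfc < -lfc_abs, "down", "none"))
}

#' Gene IDs called up or down
#' @param de a `de_table` from [run_diffexpr()].
#' @return character vector of DEG IDs.
#' @export
deg_ids <- function(de) de$gene[de$call != "none"]
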