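#' Pairwise Pearson correlation between two layers
#'
#' Correlates every gene of layer A with every gene of layer B on
#' `log2(x + 1)` values over the shared samples (at least 4). Two-sided
#' p-values come from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom; `|r| = 1` gives `p = 0`. Zero-variance genes are
#' skipped with a message.
#'
#' @param a,b expression matrices (linear scale) of two layers.
#' @param samples sample IDs to use (default: the shared columns —
#'   typically restrict to tumors).
#' @return data.frame of class `correlation_table`: `gene_a`, `gene_b`,
#'   `r`, `p`, `n`.
#' @export
pairwise_correlation <- function(a, b, samples = intersect(colnames(a),
                                                           colnames(b))) {
  if (length(samples) < 4) stop("need at least 4 shared samples")
  xa <- log2(as_plain_matrix(a)[, samples, drop = FALSE] + 1)
  xb <- log2(as_plain_matrix(b)[, samples, drop = FALSE] + 1)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  if (any(va == 0)) {
    message(sum(va == 0), " zero-variance gene(s) skipped in layer A")
    xa <- xa[va > 0, , drop = FALSE]
  }
  if (any(vb == 0)) {
    message(sum(vb == 0), " zero-variance gene(s) skipped in layer B")
    xb <- xb[vb > 0, , drop = FALSE]
  }
  if (nrow(xa) == 0 || nrow(xb) == 0) stop("no genes left to correlate")
  n <- length(samples)
  R <- cor(t(xa), t(xb))
  R <- pmin(pmax(R, -1), 1)
  tstat <- R * sqrt(n - 2) / sqrt(pmax(1 - R^2, 0))
  P <- 2 * pt(-abs(tstat), df = n - 2)
  P[abs(R) == 1] <- 0
  out <- data.frame(gene_a = rep(rownames(R), times = ncol(R)),
                    gene_b = rep(colnames(R), each = nrow(R)),
                    r = as.vector(R), p = as.vector(P), n = n,
                    row.names = NULL)
  structure(out, class = c("correlation_table", "data.frame"))
}

#' Filter a correlation table to co-expressed pairs
#'
#' Keeps pairs with `|r| >= r_min` and `p < p_max` (inclusive on r, strict
#' on p, following the conventional printed thresholds).
#'
#' @param ct a [pairwise_correlation()] table.
#' @param r_min,p_max thresholds.
#' @return the filtered table.
#' @export
filter_coexpressed <- function(ct, r_min = 0.4, p_max = 0.05) {
  out <- ct[abs(ct$r) >= r_min & ct$p < p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer miRNA-mediated lncRNA-mRNA triplets
#'
#' For every co-expressed lncRNA-mRNA pair and every miRNA co-expressed
#' with both members, emits the triplet (miRNA, lncRNA, mRNA) with all
#' three correlations. Enumeration is exhaustive over the supplied pair
#' sets and deduplicated.
#'
#' @param lnc_mrna filtered pair table with `gene_a` = lncRNA, `gene_b` =
#'   mRNA.
#' @param mir_lnc filtered pair table with `gene_a` = miRNA, `gene_b` =
#'   lncRNA.
#' @param mir_mrna filtered pair table with `gene_a` = miRNA, `gene_b` =
#'   mRNA.
#' @return data.frame of class `triplet_network`: `mirna`, `lncrna`,
#'   `mrna`, and `r`/`p` for each of the three edges (`_ml` miRNA-lncRNA,
#'   `_mm` miRNA-mRNA, `_lm` lncRNA-mRNA).
#' @export
infer_triplets <- function(lnc_mrna, mir_lnc, mir_mrna) {
  lm <- data.frame(lncrna = lnc_mrna$gene_a, mrna = lnc_mrna$gene_b,
                   r_lm = lnc_mrna$r, p_lm = lnc_mrna$p)
  ml <- data.frame(mirna = mir_lnc$gene_a, lncrna = mir_lnc$gene_b,
                   r_ml = mir_lnc$r, p_ml = mir_lnc$p)
  mm <- data.frame(mirna = mir_mrna$gene_a, mrna = mir_mrna$gene_b,
                   r_mm = mir_mrna$r, p_mm = mir_mrna$p)
  step1 <- merge(lm, ml, by = "lncrna")
  trip <- merge(step1, mm, by = c("mirna", "mrna"))
  trip <- unique(trip[, c("mirna", "lncrna", "mrna",
                          "r_ml", "p_ml", "r_mm", "p_mm", "r_lm", "p_lm")])
  trip <- trip[order(trip$mirna, trip$lncrna, trip$mrna), , drop = FALSE]
  rownames(trip) <- NULL
  structure(trip, class = c("triplet_network", "data.frame"))
}

#' Validate triplets against a miRNA-target evidence table
#'
#' A triplet is validated when its miRNA-mRNA edge is supported in at
#' least `mrna_min_db` of the six database columns and its miRNA-lncRNA
#' edge in at least `lnc_min_db` of the three designated lncRNA-evidence
#' columns. Edges absent from the table count as zero support.
#'
#' @param net a [infer_triplets()] network.
#' @param evidence data.frame with columns `mirna`, `target` and the six
#'   0/1 database flags (see [generate_target_db()]).
#' @param mrna_min_db,lnc_min_db support thresholds.
#' @param db_cols the six database column names.
#' @param lnc_db_cols the designated lncRNA-evidence subset.
#' @return the network with `db_mm`, `db_ml` support counts and a
#'   `validated` logical column.
#' @export
validate_triplets <- function(net, evidence, mrna_min_db = 4, lnc_min_db = 1,
                              db_cols = c("miRWalk", "miRanda", "miRDB",
                                          "miRNAMap", "RNA22", "Targetscan"),
                              lnc_db_cols = c("miRWalk", "miRanda",
                                              "Targetscan")) {
  need <- c("mirna", "target", db_cols)
  if (!all(need %in% colnames(evidence)))
    stop("evidence table is missing columns: ",
         paste(setdiff(need, colnames(evidence)), collapse = ", "))
  if (!all(lnc_db_cols %in% db_cols))
    stop("lnc_db_cols must be a subset of db_cols")
  key <- paste(evidence$mirna, evidence$target)
  support <- function(mir, target, cols) {
    i <- match(paste(mir, target), key)
    ifelse(is.na(i), 0L,
           as.integer(rowSums(evidence[i, cols, drop = FALSE], na.rm = TRUE)))
  }
  net$db_mm <- support(net$mirna, net$mrna, db_cols)
  net$db_ml <- support(net$mirna, net$lncrna, lnc_db_cols)
  net$validated <- net$db_mm >= mrna_min_db & net$db_ml >= lnc_min_db
  net
}

fmt_num <- function(x) sprintf("%.17g", x)

triplet_edges <- function(net) {
  edge <- function(src, tgt, type, r, p) {
    data.frame(source = src, target = tgt, edge_type = type,
               r = r, p = p, sign = ifelse(r >= 0, "+", "-"))
  }
  e <- rbind(edge(net$mirna, net$lncrna, "mirna-lncrna", net$r_ml, net$p_ml),
             edge(net$mirna, net$mrna, "mirna-mrna", net$r_mm, net$p_mm),
             edge(net$lncrna, net$mrna, "lncrna-mrna", net$r_lm, net$p_lm))
  e <- unique(e)
  e <- e[order(e$edge_type, e$source, e$target), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Export a triplet network as edge-list files
#'
#' Writes `<path>.tsv` (source, target, edge_type, r, p, sign; numbers in
#' full round-trip precision) and `<path>.sif`. The TSV round-trips
#' losslessly through [read_network()].
#'
#' @param net a [infer_triplets()] network (nonempty rows write edges; an
#'   empty network writes a header-only file with a warning).
#' @param path output path prefix (without extension).
#' @return invisibly, the two written paths.
#' @export
export_network <- function(net, path) {
  tsv <- paste0(path, ".tsv")
  sif <- paste0(path, ".sif")
  if (nrow(net) == 0) {
    warning("empty network; writing header only")
    writeLines("source\ttarget\tedge_type\tr\tp\tsign", tsv)
    writeLines(character(0), sif)
    return(invisible(c(tsv = tsv, sif = sif)))
  }
  e <- triplet_edges(net)
  lines <- c("source\ttarget\tedge_type\tr\tp\tsign",
             paste(e$source, e$target, e$edge_type,
                   fmt_num(e$r), fmt_num(e$p), e$sign, sep = "\t"))
  writeLines(lines, tsv)
  writeLines(paste(e$source, e$edge_type, e$target, sep = "\t"), sif)
  invisible(c(tsv = tsv, sif = sif))
}

#' Read an exported edge list back
#'
#' @param path path to the `.tsv` written by [export_network()].
#' @return edge data.frame (`source`, `target`, `edge_type`, `r`, `p`,
#'   `sign`).
#' @export
read_network <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "character",
                            "numeric", "numeric", "character"))
}

#' Write an edge data.frame (as read by [read_network()]) back to TSV
#' @param edges edge data.frame.
#' @param path output `.tsv` path.
#' @export
write_network_edges <- function(edges, path) {
  lines <- c("source\ttarget\tedge_type\tr\tp\tsign",
             paste(edges$source, edges$target, edges$edge_type,
                   fmt_num(edges$r), fmt_num(edges$p), edges$sign,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
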