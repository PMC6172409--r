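as_expr <- function(rows, samples, layer) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- samples
  expr_matrix(m, layer)
}

test_that("pairwise correlation reports r, p and n correctly", {
  s <- paste0("S", 1:25)
  pair <- exact_corr_pair(25, 0.4, seed = 2)
  a <- as_expr(list("mirna:m1" = 2^(pair$x + 5) - 1), s, "mirna")
  b <- as_expr(list("mrna:g1" = 2^(pair$y + 5) - 1), s, "mrna")
  ct <- pairwise_correlation(a, b)
  expect_equal(ct$r, 0.4, tolerance = 1e-10)
  expect_equal(ct$p, 0.0476, tolerance = 1e-2)
  expect_equal(ct$n, 25)
  # a gene correlated with itself across layers: r = 1, p = 0
  ct_self <- pairwise_correlation(a, as_expr(list("mrna:twin" = 2^(pair$x + 5) - 1),
                                             s, "mrna"))
  expect_equal(ct_self$r, 1)
  expect_equal(ct_self$p, 0)
  expect_error(pairwise_correlation(a[, 1:3, drop = FALSE],
                                    b[, 1:3, drop = FALSE]), "4 shared")
  # zero-variance genes are skipped with a message
  flat <- as_expr(list("mirna:m1" = 2^(pair$x + 5) - 1,
                       "mirna:flat" = rep(3, 25)), s, "mirna")
  expect_message(ct2 <- pairwise_correlation(flat, b), "zero-variance")
  expect_false("mirna:flat" %in% ct2$gene_a)
})

test_that("co-expression filter is inclusive on r and strict on p", {
  ct <- data.frame(gene_a = letters[1:4], gene_b = LETTERS[1:4],
                   r = c(0.4, 0.39, 0.9, -0.45),
                   p = c(0.01, 0.001, 0.06, 0.02), n = 25)
  out <- filter_coexpressed(ct, r_min = 0.4, p_max = 0.05)
  expect_equal(out$gene_a, c("a", "d"))
})

test_that("triplet inference joins the three pair sets exhaustively", {
  lm <- data.frame(gene_a = "lncrna:L1", gene_b = "mrna:M1", r = 0.5, p = 0.01)
  ml <- data.frame(gene_a = "mirna:u1", gene_b = "lncrna:L1", r = -0.5, p = 0.01)
  mm <- data.frame(gene_a = "mirna:u1", gene_b = "mrna:M1", r = -0.6, p = 0.01)
  net <- infer_triplets(lm, ml, mm)
  expect_equal(nrow(net), 1)
  expect_equal(net$mirna, "mirna:u1")
  expect_equal(net$r_lm, 0.5)
  # missing miRNA-mRNA edge: no triplet
  net0 <- infer_triplets(lm, ml, mm[0, , drop = FALSE])
  expect_equal(nrow(net0), 0)
})

test_that("triplet inference equals the brute-force triple loop", {
  set.seed(15)
  for (i in 1:10) {
    mk_pairs <- function(as, bs, keep) {
      g <- expand.grid(gene_a = as, gene_b = bs,
                       stringsAsFactors = FALSE)
      g <- g[runif(nrow(g)) < keep, , drop = FALSE]
      g$r <- runif(nrow(g), 0.4, 1) * sample(c(-1, 1), nrow(g), TRUE)
      g$p <- runif(nrow(g), 0, 0.05)
      g
    }
    mirs <- paste0("mirna:u", 1:6)
    lncs <- paste0("lncrna:L", 1:8)
    mrnas <- paste0("mrna:M", 1:10)
    lm <- mk_pairs(lncs, mrnas, 0.3)
    ml <- mk_pairs(mirs, lncs, 0.3)
    mm <- mk_pairs(mirs, mrnas, 0.3)
    net <- infer_triplets(lm, ml, mm)
    expect_equal(paste(net$mirna, net$lncrna, net$mrna),
                 triplets_bruteforce(lm, ml, mm))
  }
})

test_that("raising the correlation threshold never adds triplets", {
  d <- generate_dataset(tiny_cfg(n_tumor = 80))
  tumors <- names(d$truth$subtype)
  ct_lm <- pairwise_correlation(d$lncrna[, tumors], d$mrna[, tumors])
  ct_ml <- pairwise_correlation(d$mirna[, tumors], d$lncrna[, tumors])
  ct_mm <- pairwise_correlation(d$mirna[, tumors], d$mrna[, tumors])
  key <- function(net) paste(net$mirna, net$lncrna, net$mrna)
  prev <- NULL
  for (r_min in c(0.3, 0.4, 0.5, 0.6)) {
    net <- infer_triplets(filter_coexpressed(ct_lm, r_min),
                          filter_coexpressed(ct_ml, r_min),
                          filter_coexpressed(ct_mm, r_min))
    if (!is.null(prev)) expect_true(all(key(net) %in% prev))
    prev <- key(net)
  }
})

test_that("database validation applies the 4-of-6 and 1-of-3 rules", {
  net <- data.frame(mirna = "mirna:u1", lncrna = "lncrna:L1", mrna = "mrna:M1",
                    r_ml = -0.5, p_ml = 0.01, r_mm = -0.6, p_mm = 0.01,
                    r_lm = 0.5, p_lm = 0.01)
  ev_row <- function(mir, tgt, type, flags) {
    out <- data.frame(mirna = mir, target = tgt, target_type = type)
    dbs <- c("miRWalk", "miRanda", "miRDB", "miRNAMap", "RNA22", "Targetscan")
    for (i in seq_along(dbs)) out[[dbs[i]]] <- flags[i]
    out
  }
  ev4 <- rbind(ev_row("mirna:u1", "mrna:M1", "mrna", c(1, 1, 1, 1, 0, 0)),
               ev_row("mirna:u1", "lncrna:L1", "lncrna", c(1, 0, 0, 0, 0, 0)))
  expect_true(validate_triplets(net, ev4)$validated)
  ev3 <- ev4; ev3[1, "miRNAMap"] <- 0
  expect_false(validate_triplets(net, ev3)$validated)
  # lncRNA support outside the designated columns does not count
  ev_bad_lnc <- rbind(ev4[1, ], ev_row("mirna:u1", "lncrna:L1", "lncrna",
                                       c(0, 0, 1, 1, 1, 0)))
  expect_false(validate_triplets(net, ev_bad_lnc)$validated)
  # absent evidence rows count as zero support
  expect_false(validate_triplets(net, ev4[1, , drop = FALSE])$validated)
  expect_error(validate_triplets(net, ev4[, 1:4]), "missing columns")
})

test_that("planted triplets are recovered exactly through the full chain", {
  d <- generate_dataset(tiny_cfg(n_tumor = 200, seed = 77))
  tumors <- names(d$truth$subtype)
  ct_lm <- pairwise_correlation(d$lncrna[, tumors], d$mrna[, tumors])
  ct_ml <- pairwise_correlation(d$mirna[, tumors], d$lncrna[, tumors])
  ct_mm <- pairwise_correlation(d$mirna[, tumors], d$mrna[, tumors])
  net <- infer_triplets(filter_coexpressed(ct_lm), filter_coexpressed(ct_ml),
                        filter_coexpressed(ct_mm))
  ev <- generate_target_db(d$truth, decoy_fraction = 1, seed = 78)
  val <- validate_triplets(net, ev)
  got <- paste(val$mirna[val$validated], val$lncrna[val$validated],
               val$mrna[val$validated])
  want <- paste(d$truth$triplets$mirna, d$truth$triplets$lncrna,
                d$truth$triplets$mrna)
  expect_setequal(got, want)
})

test_that("network export round-trips losslessly", {
  net <- data.frame(mirna = "mirna:u1", lncrna = "lncrna:L1", mrna = "mrna:M1",
                    r_ml = -0.512345678901234, p_ml = 0.0123,
                    r_mm = -0.6, p_mm = 1e-7, r_lm = 1 / 3, p_lm = 0.04)
  prefix <- file.path(tempdir(), "net_test")
  paths <- export_network(net, prefix)
  edges <- read_network(paths[["tsv"]])
  expect_equal(nrow(edges), 3)
  # write -> read -> write produces identical bytes
  second <- file.path(tempdir(), "net_test2.tsv")
  write_network_edges(edges, second)
  expect_identical(readLines(paths[["tsv"]]), readLines(second))
  sif <- readLines(paths[["sif"]])
  expect_length(sif, 3)
  empty <- net[0, , drop = FALSE]
  expect_warning(export_network(empty, file.path(tempdir(), "net_empty")),
                 "empty")
})
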