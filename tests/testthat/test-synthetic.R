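test_that("identical seeds give bit-identical datasets, different seeds differ", {
  d1 <- generate_dataset(tiny_cfg())
  d2 <- generate_dataset(tiny_cfg())
  expect_identical(d1, d2)
  d3 <- generate_dataset(tiny_cfg(seed = 43L))
  expect_false(identical(d1$mrna, d3$mrna))
  # byte-identical after serialization too
  f1 <- tempfile(); f2 <- tempfile()
  write_dataset(d1, f1); write_dataset(d2, f2)
  for (f in c("mrna.tsv", "annotation.tsv", "truth.json"))
    expect_identical(readLines(file.path(f1, f)), readLines(file.path(f2, f)))
})

test_that("every truth ID exists in the emitted matrices and spans layers", {
  d <- generate_dataset(tiny_cfg())
  all_genes <- c(rownames(d$mrna), rownames(d$mirna), rownames(d$lncrna))
  expect_true(all(d$truth$de_genes$gene %in% all_genes))
  expect_true(all(d$truth$prognostic$gene %in% all_genes))
  tr <- d$truth$triplets
  expect_true(all(startsWith(tr$mirna, "mirna:")))
  expect_true(all(startsWith(tr$lncrna, "lncrna:")))
  expect_true(all(startsWith(tr$mrna, "mrna:")))
  expect_true(all(tr$mirna %in% rownames(d$mirna)))
  expect_setequal(names(d$truth$subtype),
                  d$annotation$sample[d$annotation$group == "tumor"])
  expect_true(all(d$mrna >= 0) && all(is.finite(d$mrna)))
})

test_that("strong subtype separation makes hierarchical clustering recover labels exactly", {
  cfg <- tiny_cfg(n_tumor = 100, k_true = 2, subtype_shift = 3,
                  noise_sd = 0.5)
  d <- generate_dataset(cfg)
  tumors <- names(d$truth$subtype)
  x <- cluster_input(d$mrna[, tumors])
  labs <- hclust_cut(pearson_distance(x), "complete", k = 2)
  expect_equal(mclust::adjustedRandIndex(labs, d$truth$subtype), 1)
})

test_that("zero subtype shift leaves no expected difference between planted subtypes", {
  d <- generate_dataset(tiny_cfg(subtype_shift = 0, n_tumor = 60,
                                 n_triplets = 0, de_fraction = 0))
  tumors <- names(d$truth$subtype)
  g <- factor(d$truth$subtype)
  x <- log2(d$mrna[, tumors] + 1)
  p <- apply(x, 1, function(v) t.test(v ~ g)$p.value)
  # nominal-level false positives only
  expect_lt(mean(p < 0.05), 0.15)
})

test_that("planted triplet pairs reach the target correlation", {
  cfg <- tiny_cfg(n_tumor = 200, triplet_r = 0.7, seed = 5L)
  d <- generate_dataset(cfg)
  tumors <- names(d$truth$subtype)
  tr <- d$truth$triplets
  x <- function(layer, g) log2(as.numeric(d[[layer]][g, tumors]) + 1)
  for (i in seq_len(nrow(tr))) {
    r_ml <- cor(x("mirna", tr$mirna[i]), x("lncrna", tr$lncrna[i]))
    r_mm <- cor(x("mirna", tr$mirna[i]), x("mrna", tr$mrna[i]))
    r_lm <- cor(x("lncrna", tr$lncrna[i]), x("mrna", tr$mrna[i]))
    expect_equal(r_ml, 0.7 * tr$sign_mirna_lncrna[i], tolerance = 0.15 / 0.7)
    expect_equal(r_mm, 0.7 * tr$sign_mirna_mrna[i], tolerance = 0.15 / 0.7)
    expect_equal(r_lm, 0.7 * tr$sign_lncrna_mrna[i], tolerance = 0.15 / 0.7)
  }
})

test_that("triplet correlation converges to the target at large n", {
  cfg <- tiny_cfg(n_tumor = 1000, n_normal = 2,
                  n_genes = c(mrna = 12, mirna = 8, lncrna = 10),
                  n_triplets = 4, triplet_r = 0.7, seed = 11L)
  d <- generate_dataset(cfg)
  tumors <- names(d$truth$subtype)
  tr <- d$truth$triplets
  for (i in seq_len(nrow(tr))) {
    r <- cor(log2(as.numeric(d$mirna[tr$mirna[i], tumors]) + 1),
             log2(as.numeric(d$mrna[tr$mrna[i], tumors]) + 1))
    expect_equal(abs(r), 0.7, tolerance = 0.05 / 0.7)
  }
})

test_that("increasing subtype shift never decreases clustering recovery on average", {
  shifts <- c(0.25, 0.75, 1.5, 3)
  mean_ari <- vapply(shifts, function(sh) {
    mean(vapply(1:10, function(s) {
      d <- generate_dataset(tiny_cfg(subtype_shift = sh, seed = s,
                                     n_tumor = 40))
      tumors <- names(d$truth$subtype)
      labs <- hclust_cut(pearson_distance(cluster_input(d$mrna[, tumors])),
                         "complete", 2)
      mclust::adjustedRandIndex(labs, d$truth$subtype)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) >= -1e-8))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(triplet_r = 1), "triplet_r")
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(generate_dataset(tiny_cfg(n_triplets = 1000)), "sizing|exceeds")
})

test_that("survival generator honours censoring and hazard settings", {
  cfg <- tiny_cfg(censor_rate = 0)
  s <- generate_survival(rep(1:2, 50), cfg, seed = 3)
  expect_true(all(s$event == 1L))
  expect_true(all(s$time > 0))
  cfg2 <- tiny_cfg(censor_rate = 0.3)
  s2 <- generate_survival(rep(1L, 4000), cfg2, seed = 3)
  expect_equal(mean(s2$event == 0), 0.3, tolerance = 0.1)
  cfg_bad <- tiny_cfg(); cfg_bad$hazard_ratio <- -1
  expect_error(generate_survival(rep(1, 10), cfg_bad), "hazard_ratio")
})

test_that("evidence table supports planted edges and starves decoys", {
  d <- generate_dataset(tiny_cfg())
  ev <- generate_target_db(d$truth, decoy_fraction = 1, seed = 2)
  dbs <- c("miRWalk", "miRanda", "miRDB", "miRNAMap", "RNA22", "Targetscan")
  lnc_dbs <- c("miRWalk", "miRanda", "Targetscan")
  tr <- d$truth$triplets
  key <- paste(ev$mirna, ev$target)
  mm <- ev[match(paste(tr$mirna, tr$mrna), key), ]
  ml <- ev[match(paste(tr$mirna, tr$lncrna), key), ]
  expect_true(all(rowSums(mm[, dbs]) >= 4))
  expect_true(all(rowSums(ml[, lnc_dbs]) >= 1))
  planted_keys <- c(paste(tr$mirna, tr$mrna), paste(tr$mirna, tr$lncrna))
  dec <- ev[!(key %in% planted_keys), ]
  expect_gt(nrow(dec), 0)
  dec_m <- dec[dec$target_type == "mrna", ]
  dec_l <- dec[dec$target_type == "lncrna", ]
  if (nrow(dec_m)) expect_true(all(rowSums(dec_m[, dbs]) <= 3))
  if (nrow(dec_l)) expect_true(all(rowSums(dec_l[, lnc_dbs]) == 0))
})
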