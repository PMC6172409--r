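# per-stage substream seeds derived from the master seed; offsets are
# arbitrary but fixed, and results stay inside 32-bit integer range
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, cluster = 37L, de = 53L,
               gsea = 71L, classify = 89L, crosstalk = 107L, survival = 131L,
               evidence = 149L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

md5_rel <- function(paths, root) {
  h <- tools::md5sum(paths)
  names(h) <- sub(paste0("^", root, "/?"), "", names(h))
  as.list(h)
}

default_gene_sets <- function(truth, genes, seed, n_random = 8,
                              random_size = 20) {
  set.seed(seed)
  sets <- list()
  prog <- truth$prognostic
  if (!is.null(prog) && nrow(prog) > 0) {
    mr <- prog[startsWith(prog$gene, "mrna:"), , drop = FALSE]
    if (sum(mr$hazard_direction == -1) > 0)
      sets$subtype1_markers <- mr$gene[mr$hazard_direction == -1]
    if (sum(mr$hazard_direction == 1) > 0)
      sets$subtype2_markers <- mr$gene[mr$hazard_direction == 1]
  }
  for (i in seq_len(n_random))
    sets[[sprintf("random_set_%02d", i)]] <- sample(genes,
                                                    min(random_size,
                                                        length(genes)))
  sets
}

#' Run the full subtype-discovery and crosstalk analysis
#'
#' Orchestrates simulate -> preprocess -> per-layer consensus clustering ->
#' cluster-of-clusters -> K selection -> differential expression -> GSEA ->
#' classification evaluation -> DEFG intersection -> triplet inference and
#' validation -> survival/clinical readouts, writing every artifact plus a
#' manifest (stage, parameters, seed, md5 of outputs) and a run report.
#' Identical configuration and seed give byte-identical manifests.
#'
#' @param sim a [sim_config()]; its seed is replaced by the simulate-stage
#'   substream of `seed`.
#' @param out_dir output directory (created).
#' @param seed master seed; each stage uses a named substream.
#' @param k_max,reps,p_item consensus-clustering parameters.
#' @param mean_filter,top_mad preprocessing parameters (`top_mad` named per
#'   layer; capped at the genes available).
#' @param fdr,lfc DEG thresholds.
#' @param gene_sets named list for GSEA, or `NULL` to build a default
#'   collection from the planted truth plus random sets.
#' @param n_perm,gsea_min_size GSEA permutation count and set-size floor.
#' @param train_frac,folds classification protocol parameters.
#' @param backend classifier backend (see [backend_logistic()]).
#' @param r_min,p_max co-expression thresholds.
#' @param decoy_fraction decoy fraction for the synthetic evidence table.
#' @param horizon survival-rate horizon in the dataset's time unit.
#' @return invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(sim = sim_config(), out_dir, seed = 1L,
                         k_max = 6, reps = 50, p_item = 0.8,
                         mean_filter = 0.25,
                         top_mad = c(mrna = 3000, mirna = 300, lncrna = 3000),
                         fdr = 0.05, lfc = 0.57,
                         gene_sets = NULL, n_perm = 1000, gsea_min_size = 15,
                         train_frac = 0.6, folds = 10,
                         backend = backend_logistic(),
                         r_min = 0.4, p_max = 0.05, decoy_fraction = 0.5,
                         horizon = 60) {
  if (k_max < 2) stop("k_max must be at least 2")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = as.integer(seed), stages = list())
  add_stage <- function(stage, params, paths) {
    manifest$stages[[stage]] <<- list(
      stage = stage, seed = stage_seed(seed, stage), params = params,
      outputs = md5_rel(paths, out_dir))
  }
  layers <- c("mrna", "mirna", "lncrna")

  ## simulate
  sim$seed <- stage_seed(seed, "simulate")
  data <- generate_dataset(sim)
  paths <- write_dataset(data, file.path(out_dir, "data"))
  add_stage("simulate", unclass(sim), unname(paths))
  ann <- data$annotation
  tumors <- ann$sample[ann$group == "tumor"]

  ## preprocess (tumors only feed the clustering)
  inputs <- lapply(setNames(layers, layers), function(l)
    preprocess_layer(data[[l]], samples = tumors,
                     mean_filter = mean_filter,
                     top_mad = top_mad[[l]]))
  pp_paths <- vapply(layers, function(l) {
    p <- file.path(out_dir, paste0("input_", l, ".tsv"))
    write_expression_tsv(inputs[[l]], p)
    p
  }, character(1))
  add_stage("preprocess",
            list(mean_filter = mean_filter, top_mad = as.list(top_mad)),
            pp_paths)

  ## consensus clustering + CoC + K selection
  disc <- discover_subtypes(inputs, k_max = k_max, reps = reps,
                            p_item = p_item,
                            seed = stage_seed(seed, "cluster"))
  labels <- disc$labels
  met_path <- file.path(out_dir, "k_metrics.tsv")
  write.table(disc$coc_metrics, met_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lab_path <- file.path(out_dir, "subtype_labels.tsv")
  write.table(data.frame(sample = names(labels), subtype = labels),
              lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  add_stage("cluster",
            list(k_max = k_max, reps = reps, p_item = p_item,
                 layer_k = as.list(disc$layer_k),
                 votes = as.list(disc$selection$votes),
                 selected_k = disc$selected_k),
            c(met_path, lab_path))
  ari <- mclust::adjustedRandIndex(labels[names(data$truth$subtype)],
                                   data$truth$subtype)

  ## differential expression per layer (tumor vs normal)
  groups_tn <- factor(ann$group, levels = c("normal", "tumor"))
  de_tables <- list(); de_paths <- character(0)
  for (l in layers) {
    de <- run_diffexpr(data[[l]], groups_tn, fdr = fdr, lfc_abs = lfc)
    de_tables[[l]] <- de
    p <- file.path(out_dir, paste0("de_", l, ".tsv"))
    write.table(de, p, sep = "\t", quote = FALSE, row.names = FALSE)
    de_paths <- c(de_paths, p)
  }
  degs <- unlist(lapply(de_tables, deg_ids), use.names = FALSE)
  add_stage("de", list(fdr = fdr, lfc = lfc), de_paths)

  ## GSEA on the subtype contrast (mRNA layer, clusters 1 vs 2)
  gsea_path <- file.path(out_dir, "gsea.tsv")
  gsea_res <- NULL
  sub12 <- names(labels)[labels %in% c(1, 2)]
  if (length(unique(labels[sub12])) == 2 && length(sub12) >= 6) {
    if (is.null(gene_sets))
      gene_sets <- default_gene_sets(data$truth, rownames(data$mrna),
                                     stage_seed(seed, "gsea"))
    gmat <- log2(as_plain_matrix(data$mrna)[, sub12, drop = FALSE] + 1)
    gsea_res <- run_gsea(gmat, factor(labels[sub12]), gene_sets,
                         n_perm = n_perm, min_size = gsea_min_size,
                         seed = stage_seed(seed, "gsea"))
    write.table(gsea_res, gsea_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add_stage("gsea", list(n_perm = n_perm, min_size = gsea_min_size),
              gsea_path)
  }

  ## classification evaluation per layer + feature genes
  cls_seed <- stage_seed(seed, "classify")
  y <- factor(labels[tumors])
  auc <- list(); cv_acc <- list(); feature_genes <- character(0)
  if (nlevels(y) >= 2) {
    y2 <- droplevels(y[y %in% levels(y)[1:2]])
    for (l in layers) {
      x <- t(inputs[[l]][, names(y2), drop = FALSE])
      sp <- stratified_split(rownames(x), y2, train_frac = train_frac,
                             seed = cls_seed)
      model <- backend$fit(x[sp$train, , drop = FALSE], y2[sp$train])
      sc <- backend$score(model, x[sp$test, , drop = FALSE])
      auc[[l]] <- roc_auc(sc, y2[sp$test])$auc
      cv_acc[[l]] <- cross_validate(backend, x, y2, folds = folds,
                                    seed = cls_seed)$mean_accuracy
      feature_genes <- c(feature_genes,
                         select_feature_genes(backend, model))
    }
  }
  add_stage("classify",
            list(train_frac = train_frac, folds = folds,
                 auc = auc, cv_accuracy = cv_acc),
            character(0))

  ## DEFGs and the crosstalk network
  defgs <- suppressWarnings(defg_intersect(feature_genes, degs))
  net_prefix <- file.path(out_dir, "network")
  evidence <- generate_target_db(data$truth,
                                 decoy_fraction = decoy_fraction,
                                 seed = stage_seed(seed, "evidence"))
  net <- validated <- NULL
  if (all(lengths(defgs) > 0)) {
    sub_m <- function(l, ids) data[[l]][ids, tumors, drop = FALSE]
    ct_lm <- pairwise_correlation(sub_m("lncrna", defgs$lncrna),
                                  sub_m("mrna", defgs$mrna))
    ct_ml <- pairwise_correlation(sub_m("mirna", defgs$mirna),
                                  sub_m("lncrna", defgs$lncrna))
    ct_mm <- pairwise_correlation(sub_m("mirna", defgs$mirna),
                                  sub_m("mrna", defgs$mrna))
    net <- infer_triplets(filter_coexpressed(ct_lm, r_min, p_max),
                          filter_coexpressed(ct_ml, r_min, p_max),
                          filter_coexpressed(ct_mm, r_min, p_max))
    net <- validate_triplets(net, evidence)
    validated <- net[net$validated, , drop = FALSE]
    net_paths <- suppressWarnings(export_network(net, net_prefix))
    add_stage("crosstalk",
              list(r_min = r_min, p_max = p_max,
                   decoy_fraction = decoy_fraction),
              unname(net_paths))
  }

  ## survival and clinical readouts
  surv_seed <- stage_seed(seed, "survival")  # reserved; stage deterministic
  tum <- ann[ann$group == "tumor", ]
  lr <- rate1 <- rate2 <- NULL
  if (length(unique(labels)) >= 2) {
    g1 <- names(labels)[labels == 1]; g2 <- names(labels)[labels == 2]
    t1 <- tum[match(g1, tum$sample), ]; t2 <- tum[match(g2, tum$sample), ]
    lr <- logrank_test(t1$time, t1$event, t2$time, t2$event)
    rate1 <- survival_rate_at(km_curve(t1$time, t1$event), horizon)
    rate2 <- survival_rate_at(km_curve(t2$time, t2$event), horizon)
  }
  clin <- list()
  for (cov in c("grade", "stage")) {
    tab <- table(labels[tum$sample], tum[[cov]])
    clin[[cov]] <- tryCatch(chisq_clinical(tab)$p, error = function(e) NA)
  }

  ## truth recovery summaries
  truth_trip <- data$truth$triplets
  trip_key <- function(d) paste(d$mirna, d$lncrna, d$mrna)
  tp <- if (!is.null(validated)) sum(trip_key(validated) %in%
                                       trip_key(truth_trip)) else 0
  precision <- if (!is.null(validated) && nrow(validated) > 0)
    tp / nrow(validated) else NA
  recall <- if (nrow(truth_trip) > 0) tp / nrow(truth_trip) else NA

  report <- list(
    selected_k = disc$selected_k,
    votes = as.list(disc$selection$votes),
    layer_k = as.list(disc$layer_k),
    pac_selected_k =
      disc$coc_metrics$PAC[disc$coc_metrics$K == disc$selected_k],
    subtype_ari = ari,
    n_deg = lapply(de_tables, function(d) sum(d$call != "none")),
    auc = auc, cv_accuracy = cv_acc,
    n_feature_genes = length(unique(feature_genes)),
    n_defg = lapply(defgs, length),
    n_triplets = if (is.null(net)) 0L else nrow(net),
    n_validated = if (is.null(validated)) 0L else nrow(validated),
    triplet_precision = precision, triplet_recall = recall,
    logrank_chisq = if (is.null(lr)) NA else lr$chisq,
    logrank_p = if (is.null(lr)) NA else lr$p,
    survival_rate_subtype1 = rate1, survival_rate_subtype2 = rate2,
    clinical_p = clin)
  rep_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$stages[["report"]] <- list(stage = "report", seed = surv_seed,
                                      params = list(horizon = horizon),
                                      outputs = md5_rel(rep_path, out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
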