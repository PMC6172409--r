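#' Simulation configuration for the synthetic multi-omic generator
#'
#' Defines the study conditions the generator emulates: three co-measured
#' omics layers over shared samples, planted tumor subtypes with
#' layer-specific signal, tumor-vs-normal differential genes, planted
#' miRNA-mediated lncRNA-mRNA triplets with signed correlations,
#' subtype-linked exponential survival with uniform censoring, and
#' categorical clinical covariates associated with subtype.
#'
#' All effects are defined on the log2 scale; expression is emitted on the
#' linear (FPKM/RPM-like) scale as `2^(mu + effects + N(0, noise_sd))`.
#'
#' @param n_tumor,n_normal tumor and adjacent-normal sample counts.
#' @param n_genes named counts per layer (`mrna`, `mirna`, `lncrna`).
#' @param k_true planted subtype count among tumors.
#' @param subtype_shift log2-scale mean separation of subtype-informative
#'   genes between a gene's own subtype and the rest.
#' @param subtype_frac fraction of each layer's genes that carry subtype
#'   signal.
#' @param de_fraction,de_lfc fraction of genes differentially expressed
#'   tumor-vs-normal and their log2 fold change (half up, half down).
#' @param n_triplets number of planted miRNA-mediated lncRNA-mRNA triplets.
#' @param triplet_r target absolute pairwise Pearson correlation within a
#'   triplet (|triplet_r| < 1).
#' @param triplet_signs named signs (+1/-1) of the per-layer latent-factor
#'   loadings; pairwise correlation signs are products of member signs. The
#'   default (miRNA -1, lncRNA +1, mRNA +1) gives the classic pattern of a
#'   miRNA anti-correlated with both of its targets, which are positively
#'   correlated with each other.
#' @param noise_sd log2-scale residual standard deviation (> 0).
#' @param hazard_ratio hazard of subtype 2 relative to the other subtypes
#'   (> 0).
#' @param censor_rate target fraction of censored tumors in the reference
#'   arm (0..1).
#' @param follow_up_max administrative follow-up horizon; censoring times
#'   are uniform on (0, follow_up_max). Time unit is arbitrary (months by
#'   convention here, so a 5-year horizon is 60).
#' @param clinical_odds odds multiplier linking clinical covariate levels to
#'   subtype 2 (for chi-square testing).
#' @param seed integer master seed; equal seeds give bit-identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_tumor = 120, n_normal = 20,
                       n_genes = c(mrna = 300, mirna = 80, lncrna = 150),
                       k_true = 2, subtype_shift = 1.5, subtype_frac = 0.2,
                       de_fraction = 0.1, de_lfc = 1.5,
                       n_triplets = 10, triplet_r = 0.7,
                       triplet_signs = c(mirna = -1, lncrna = 1, mrna = 1),
                       noise_sd = 0.5, hazard_ratio = 3, censor_rate = 0.3,
                       follow_up_max = 60, clinical_odds = 3, seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_genes = n_genes, k_true = as.integer(k_true),
              subtype_shift = subtype_shift, subtype_frac = subtype_frac,
              de_fraction = de_fraction, de_lfc = de_lfc,
              n_triplets = as.integer(n_triplets), triplet_r = triplet_r,
              triplet_signs = triplet_signs, noise_sd = noise_sd,
              hazard_ratio = hazard_ratio, censor_rate = censor_rate,
              follow_up_max = follow_up_max, clinical_odds = clinical_odds,
              seed = as.integer(seed))
  stopifnot(cfg$n_tumor >= 1, cfg$n_normal >= 1, cfg$k_true >= 1)
  if (!all(c("mrna", "mirna", "lncrna") %in% names(cfg$n_genes)))
    stop("n_genes must name mrna, mirna and lncrna counts")
  if (any(cfg$n_genes < 1)) stop("all layer gene counts must be >= 1")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop("censor_rate must be in [0, 1]")
  if (abs(cfg$triplet_r) >= 1) stop("|triplet_r| must be < 1")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$subtype_frac < 0 || cfg$subtype_frac > 1)
    stop("subtype_frac must be in [0, 1]")
  if (!all(sort(names(cfg$triplet_signs)) == c("lncrna", "mirna", "mrna")) ||
      !all(abs(cfg$triplet_signs) == 1))
    stop("triplet_signs must be named +1/-1 for mirna, lncrna, mrna")
  class(cfg) <- "sim_config"
  cfg
}

layer_prefix <- c(mrna = "mrna:", mirna = "mirna:", lncrna = "lncrna:")

#' Generate a synthetic multi-omic dataset with planted ground truth
#'
#' Emits three expression matrices (mRNA, miRNA, lncRNA) over shared
#' samples, a sample annotation table (group, subtype, survival time/event,
#' two clinical covariates), and the truth needed for recovery tests.
#'
#' Planted structure, all on the log2 scale before exponentiation:
#' per-gene baseline `mu ~ U(2, 8)`; subtype-informative genes get
#' `+subtype_shift` in their own subtype; DE genes get `+/- de_lfc` in all
#' tumors; each triplet's three member genes load on a shared standard
#' normal factor with loading `lambda = noise_sd * sqrt(r / (1 - r))` and
#' the configured signs, so pairwise correlations approach `triplet_r`
#' (tumors only). Triplet members are additionally flagged (and shifted) as
#' tumor-vs-normal DE so the feature-gene -> DE -> crosstalk path carries
#' planted signal; set `n_triplets = 0` for strict global-null runs.
#'
#' @param config a [sim_config()].
#' @return list with elements `mrna`, `mirna`, `lncrna` ([expr_matrix()]s),
#'   `annotation` (data.frame) and `truth` (list: `subtype` named integer
#'   vector over tumors, `de_genes` data.frame (gene, layer, direction),
#'   `triplets` data.frame with member IDs and pairwise signs,
#'   `prognostic` data.frame (gene, hazard_direction)).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (any(cfg$n_triplets > cfg$n_genes))
    stop("n_triplets exceeds the gene count of at least one layer")
  set.seed(cfg$seed)

  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(cfg$n_normal))
  samples <- c(tumor_ids, normal_ids)
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))

  subtype <- sample(rep_len(seq_len(cfg$k_true), cfg$n_tumor))
  names(subtype) <- tumor_ids

  lambda <- cfg$noise_sd * sqrt(cfg$triplet_r / (1 - cfg$triplet_r))
  latent <- if (cfg$n_triplets > 0)
    matrix(rnorm(cfg$n_triplets * cfg$n_tumor), cfg$n_triplets) else NULL

  layers <- list()
  de_genes <- list()
  triplet_members <- list()
  prognostic <- list()
  for (layer in c("mrna", "mirna", "lncrna")) {
    ng <- as.integer(cfg$n_genes[[layer]])
    genes <- paste0(layer_prefix[[layer]], sprintf("G%04d", seq_len(ng)))
    mu <- runif(ng, 2, 8)

    # reserve triplet members first, then draw subtype / DE genes from the rest
    trip_idx <- if (cfg$n_triplets > 0) sample(ng, cfg$n_triplets) else integer(0)
    rest <- setdiff(seq_len(ng), trip_idx)
    n_sub <- min(floor(cfg$subtype_frac * ng), length(rest))
    sub_idx <- if (n_sub > 0) sample(rest, n_sub) else integer(0)
    rest2 <- setdiff(rest, sub_idx)
    n_de <- min(floor(cfg$de_fraction * ng), length(rest2))
    de_idx <- if (n_de > 0) sample(rest2, n_de) else integer(0)

    log2x <- matrix(mu, ng, length(samples))
    dimnames(log2x) <- list(genes, samples)

    if (length(sub_idx) > 0 && cfg$k_true > 1) {
      gene_sub <- rep_len(seq_len(cfg$k_true), length(sub_idx))
      for (j in seq_along(sub_idx)) {
        hit <- tumor_ids[subtype == gene_sub[j]]
        log2x[sub_idx[j], hit] <- log2x[sub_idx[j], hit] + cfg$subtype_shift
      }
      # subtype-2 marker genes are high in the poor-prognosis arm
      prognostic[[layer]] <- data.frame(
        gene = genes[sub_idx],
        hazard_direction = ifelse(gene_sub == 2, 1L, -1L))
    }

    de_dir <- integer(0)
    if (length(de_idx) > 0) {
      de_dir <- rep_len(c(1L, -1L), length(de_idx))
      log2x[de_idx, tumor_ids] <- log2x[de_idx, tumor_ids] +
        de_dir * cfg$de_lfc
    }

    sgn <- cfg$triplet_signs[[layer]]
    if (length(trip_idx) > 0) {
      log2x[trip_idx, tumor_ids] <- log2x[trip_idx, tumor_ids] +
        sgn * lambda * latent
      # triplet members double as tumor-vs-normal DE genes
      log2x[trip_idx, tumor_ids] <- log2x[trip_idx, tumor_ids] +
        sgn * cfg$de_lfc
      triplet_members[[layer]] <- genes[trip_idx]
    }

    log2x <- log2x + matrix(rnorm(length(log2x), 0, cfg$noise_sd),
                            nrow(log2x))
    layers[[layer]] <- expr_matrix(2^log2x, layer)

    de_ids <- c(genes[de_idx], genes[trip_idx])
    de_genes[[layer]] <- data.frame(
      gene = de_ids,
      layer = rep(layer, length(de_ids)),
      direction = c(de_dir, rep(as.integer(sgn), length(trip_idx))))
  }

  surv <- generate_survival(subtype, cfg, seed = NULL)

  # two categorical clinical covariates with subtype-linked level odds
  p_grade <- plogis(qlogis(0.35) + log(cfg$clinical_odds) * (subtype == 2))
  grade <- ifelse(runif(cfg$n_tumor) < p_grade, "high", "low")
  p_stage <- plogis(qlogis(0.40) + log(cfg$clinical_odds) * (subtype == 2))
  stage <- ifelse(runif(cfg$n_tumor) < p_stage, "III-IV", "II")

  annotation <- data.frame(
    sample = samples,
    group = ifelse(is_tumor, "tumor", "normal"),
    subtype = c(subtype, rep(NA_integer_, cfg$n_normal)),
    time = c(surv$time, rep(NA_real_, cfg$n_normal)),
    event = c(surv$event, rep(NA_integer_, cfg$n_normal)),
    grade = c(grade, rep(NA_character_, cfg$n_normal)),
    stage = c(stage, rep(NA_character_, cfg$n_normal)),
    stringsAsFactors = FALSE)

  triplets <- if (cfg$n_triplets > 0) {
    s <- cfg$triplet_signs
    data.frame(mirna = triplet_members$mirna,
               lncrna = triplet_members$lncrna,
               mrna = triplet_members$mrna,
               sign_mirna_lncrna = as.integer(s[["mirna"]] * s[["lncrna"]]),
               sign_mirna_mrna = as.integer(s[["mirna"]] * s[["mrna"]]),
               sign_lncrna_mrna = as.integer(s[["lncrna"]] * s[["mrna"]]))
  } else {
    data.frame(mirna = character(0), lncrna = character(0),
               mrna = character(0), sign_mirna_lncrna = integer(0),
               sign_mirna_mrna = integer(0), sign_lncrna_mrna = integer(0))
  }

  truth <- list(
    subtype = subtype,
    de_genes = do.call(rbind, c(de_genes, make.row.names = FALSE)),
    triplets = triplets,
    prognostic = do.call(rbind, c(prognostic, make.row.names = FALSE)))

  list(mrna = layers$mrna, mirna = layers$mirna, lncrna = layers$lncrna,
       annotation = annotation, truth = truth)
}

#' Simulate subtype-linked survival times with uniform censoring
#'
#' Event times are exponential; samples in subtype 2 have hazard
#' `hazard_ratio` times the reference hazard. Censoring is administrative:
#' uniform on (0, `follow_up_max`), with the reference hazard calibrated so
#' the expected censored fraction in the reference arm equals
#' `censor_rate`. With `censor_rate = 0` no censoring is applied.
#'
#' @param labels subtype assignment (integer vector); subtype 2 is the
#'   elevated-hazard arm.
#' @param config a [sim_config()] supplying `hazard_ratio`, `censor_rate`
#'   and `follow_up_max`.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return data.frame with `time` (> 0) and `event` (1 = event, 0 =
#'   censored), one row per label.
#' @export
generate_survival <- function(labels, config, seed = config$seed) {
  stopifnot(length(labels) > 0)
  if (config$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  fmax <- config$follow_up_max
  h0 <- if (config$censor_rate > 0) {
    # solve P(censor) = (1 - exp(-h F)) / (h F) = censor_rate for h
    uniroot(function(h) (1 - exp(-h * fmax)) / (h * fmax) - config$censor_rate,
            lower = 1e-8, upper = 1e4, tol = 1e-12)$root
  } else {
    2 / fmax  # mean event time = half the follow-up window
  }
  rate <- h0 * ifelse(labels == 2, config$hazard_ratio, 1)
  tt <- rexp(n, rate)
  if (config$censor_rate > 0) {
    cc <- runif(n, 0, fmax)
    data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
  } else {
    data.frame(time = tt, event = rep(1L, n))
  }
}

#' Build a synthetic miRNA-target evidence table
#'
#' Emulates an integrated target-prediction resource with six database
#' support columns (`miRWalk`, `miRanda`, `miRDB`, `miRNAMap`, `RNA22`,
#' `Targetscan`), of which the first, second and last are the designated
#' lncRNA-evidence columns. Planted miRNA-mRNA edges receive support in at
#' least four of the six databases; planted miRNA-lncRNA edges in at least
#' one of the three designated ones; decoy edges stay below those
#' thresholds.
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param decoy_fraction decoy rows added, as a fraction of planted rows.
#' @param seed RNG seed.
#' @return data.frame: `mirna`, `target`, `target_type`, six 0/1 database
#'   columns.
#' @export
generate_target_db <- function(truth, decoy_fraction = 0.5, seed = 1L) {
  trip <- truth$triplets
  if (nrow(trip) == 0) stop("truth contains no planted triplets")
  set.seed(seed)
  dbs <- c("miRWalk", "miRanda", "miRDB", "miRNAMap", "RNA22", "Targetscan")
  lnc_dbs <- c("miRWalk", "miRanda", "Targetscan")

  row_for <- function(mir, target, type) {
    flags <- setNames(integer(6), dbs)
    if (type == "mrna") {
      k <- sample(4:6, 1)
      flags[sample(dbs, k)] <- 1L
    } else {
      k <- sample(1:3, 1)
      flags[sample(lnc_dbs, k)] <- 1L
    }
    data.frame(mirna = mir, target = target, target_type = type,
               as.list(flags), check.names = FALSE)
  }
  decoy_for <- function(mir, target, type) {
    flags <- setNames(integer(6), dbs)
    if (type == "mrna") {
      k <- sample(0:3, 1)
      if (k > 0) flags[sample(dbs, k)] <- 1L
    } else {
      k <- sample(0:3, 1)  # support only outside the designated columns
      if (k > 0) flags[sample(setdiff(dbs, lnc_dbs), k)] <- 1L
    }
    data.frame(mirna = mir, target = target, target_type = type,
               as.list(flags), check.names = FALSE)
  }

  planted <- rbind(
    do.call(rbind, Map(row_for, trip$mirna, trip$mrna, "mrna")),
    do.call(rbind, Map(row_for, trip$mirna, trip$lncrna, "lncrna")))

  n_decoy <- round(decoy_fraction * nrow(planted))
  decoys <- NULL
  if (n_decoy > 0) {
    mirs <- unique(trip$mirna)
    targets <- unique(c(trip$mrna, trip$lncrna))
    planted_key <- paste(planted$mirna, planted$target)
    out <- list()
    while (length(out) < n_decoy) {
      mir <- sample(mirs, 1)
      tgt <- sample(targets, 1)
      key <- paste(mir, tgt)
      if (key %in% planted_key || key %in% names(out)) next
      type <- if (startsWith(tgt, "mrna:")) "mrna" else "lncrna"
      out[[key]] <- decoy_for(mir, tgt, type)
    }
    decoys <- do.call(rbind, out)
  }
  res <- rbind(planted, decoys)
  rownames(res) <- NULL
  res
}

#' Write a generated dataset to a directory
#'
#' Expression TSVs (one per layer), annotation TSV and truth JSON, in the
#' dialects read back by [read_expression_tsv()], [read_annotation_tsv()]
#' and [jsonlite::read_json()].
#'
#' @param data result of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mrna = file.path(dir, "mrna.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             lncrna = file.path(dir, "lncrna.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.json"))
  for (layer in c("mrna", "mirna", "lncrna"))
    write_expression_tsv(data[[layer]], paths[[layer]])
  write_annotation_tsv(data$annotation, paths[["annotation"]])
  truth <- data$truth
  truth$subtype <- as.list(truth$subtype)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
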