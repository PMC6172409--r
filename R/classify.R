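#' Classifier backend contract
#'
#' The evaluation protocol ([stratified_split()], [cross_validate()],
#' [roc_auc()], [select_feature_genes()]) is generic over an injected
#' backend: a list with three functions,
#' `fit(x, y)` returning a fitted model (x = samples x features matrix, y =
#' two-level factor), `score(model, x)` returning per-sample probabilities
#' of the second class in `[0, 1]`, and `importance(model)` returning a
#' named nonnegative weight per feature.
#'
#' `backend_logistic()` is a deterministic, shrinkage-free reference
#' backend: each feature gets a signal-to-noise-style weight
#' `w = (m2 - m1) / (s1 + s2 + eps)` from the training data, samples are
#' scored by `plogis` of the standardized weighted sum, and `|w|` is the
#' importance. It handles more features than samples and needs no
#' randomness.
#'
#' `backend_xgboost()` wraps a gradient-boosted tree model (package
#' `xgboost`, if installed) with defaults gamma = 1, min_child_weight = 1,
#' max_depth = 14, nrounds = 2000; importance is total gain per feature.
#'
#' @param eps variance-floor constant for the reference backend.
#' @return a backend list with `fit`, `score`, `importance`.
#' @export
backend_logistic <- function(eps = 0.01) {
  list(
    fit = function(x, y) {
      y <- as.factor(y)
      stopifnot(nlevels(y) == 2)
      g2 <- y == levels(y)[2]
      m1 <- colMeans(x[!g2, , drop = FALSE])
      m2 <- colMeans(x[g2, , drop = FALSE])
      s1 <- apply(x[!g2, , drop = FALSE], 2, sd)
      s2 <- apply(x[g2, , drop = FALSE], 2, sd)
      w <- (m2 - m1) / (s1 + s2 + eps)
      z <- drop(x %*% w)
      list(w = w, center = mean(z), scale = max(sd(z), eps),
           levels = levels(y))
    },
    score = function(model, x) {
      z <- drop(x[, names(model$w), drop = FALSE] %*% model$w)
      plogis((z - model$center) / model$scale)
    },
    importance = function(model) abs(model$w)
  )
}

#' @rdname backend_logistic
#' @param nrounds,max_depth,gamma,min_child_weight,eta boosting
#'   hyperparameters.
#' @param nthread threads (1 keeps results deterministic).
#' @export
backend_xgboost <- function(nrounds = 2000, max_depth = 14, gamma = 1,
                            min_child_weight = 1, eta = 0.3, nthread = 1) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("the 'xgboost' package is required for this backend")
  list(
    fit = function(x, y) {
      y <- as.factor(y)
      stopifnot(nlevels(y) == 2)
      dtrain <- xgboost::xgb.DMatrix(
        data = x, label = as.integer(y == levels(y)[2]))
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = max_depth, gamma = gamma,
                      min_child_weight = min_child_weight, eta = eta,
                      nthread = nthread),
        data = dtrain, nrounds = nrounds, verbose = 0)
      list(bst = bst, features = colnames(x), levels = levels(y))
    },
    score = function(model, x) {
      as.numeric(predict(model$bst,
                         xgboost::xgb.DMatrix(x[, model$features,
                                                drop = FALSE])))
    },
    importance = function(model) {
      imp <- xgboost::xgb.importance(model = model$bst)
      w <- setNames(rep(0, length(model$features)), model$features)
      w[imp$Feature] <- imp$Gain
      w
    }
  )
}

#' Stratified train/test split
#'
#' Allocates `train_frac` of each class to the training set by the
#' largest-remainder rule, so per-class proportions are preserved as
#' closely as integers allow. Deterministic given the seed.
#'
#' @param samples sample IDs.
#' @param labels class labels aligned with `samples` (both classes with
#'   >= 2 samples).
#' @param train_frac training fraction, in (0, 1).
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return list with disjoint, exhaustive `train` and `test` ID vectors.
#' @export
stratified_split <- function(samples, labels, train_frac = 0.6, seed = NULL) {
  stopifnot(length(samples) == length(labels))
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be strictly between 0 and 1")
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stop("every class needs >= 2 samples")
  if (!is.null(seed)) set.seed(seed)
  targets <- train_frac * table(labels)
  base <- floor(targets)
  total <- round(train_frac * length(samples))
  extra <- total - sum(base)
  if (extra > 0) {
    rem_order <- order(-(targets - base))
    base[rem_order[seq_len(extra)]] <- base[rem_order[seq_len(extra)]] + 1
  }
  train <- unlist(lapply(levels(labels), function(lv) {
    ids <- samples[labels == lv]
    sample(ids, base[[lv]])
  }), use.names = FALSE)
  list(train = train, test = setdiff(samples, train))
}

# stratified fold assignment, one integer fold id per sample
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (lv in levels(as.factor(labels))) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' K-fold cross-validated accuracy of a backend
#'
#' Stratified folds; per fold, the backend is fitted on the remaining
#' folds and held-out samples are classified at a 0.5 score threshold.
#' Folds whose test part lacks a class are skipped with a warning.
#'
#' @param backend a backend list (see [backend_logistic()]).
#' @param x samples x features matrix.
#' @param y two-level factor.
#' @param folds number of folds (<= n).
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return list: `mean_accuracy`, per-fold `accuracy`.
#' @export
cross_validate <- function(backend, x, y, folds = 10, seed = NULL) {
  y <- as.factor(y)
  stopifnot(folds <= nrow(x))
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, folds)
  acc <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    if (length(unique(y[test])) < 2 || length(unique(y[!test])) < 2) {
      warning("fold ", f, " lacks both classes; skipped")
      next
    }
    model <- backend$fit(x[!test, , drop = FALSE], y[!test])
    s <- backend$score(model, x[test, , drop = FALSE])
    pred <- ifelse(s >= 0.5, levels(y)[2], levels(y)[1])
    acc[f] <- mean(pred == as.character(y[test]))
  }
  list(mean_accuracy = mean(acc, na.rm = TRUE), accuracy = acc)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps all score thresholds, yielding an ROC from (0, 0) to (1, 1); the
#' AUC is the trapezoidal area, equal to the Mann-Whitney probability with
#' ties counted one half.
#'
#' @param scores numeric scores (larger = more positive-like).
#' @param labels logical/two-level labels; the second level (or `TRUE`) is
#'   the positive class.
#' @return list: `roc` data.frame (`fpr`, `tpr`), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) pos <- labels else {
    labels <- as.factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    pos <- labels == levels(labels)[2]
  }
  if (all(pos) || !any(pos)) stop("both classes must be present")
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(-scores)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores so ties contribute diagonal ROC segments
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Rank feature genes by backend importance
#'
#' Features with strictly positive importance, sorted by descending
#' weight; ties break by feature ID.
#'
#' @param backend a backend list.
#' @param model a fitted model from `backend$fit`.
#' @return character vector of feature IDs (may be empty, with a warning).
#' @export
select_feature_genes <- function(backend, model) {
  imp <- backend$importance(model)
  keep <- imp > 0
  if (!any(keep)) {
    warning("all feature importances are zero")
    return(character(0))
  }
  imp <- imp[keep]
  names(imp)[order(-imp, names(imp))]
}

#' Intersect feature genes with DEGs, per omics layer
#'
#' The differentially expressed feature genes (DEFGs) are the set
#' intersection of classifier feature genes and DEG IDs, partitioned by
#' the layer prefix of the namespaced IDs.
#'
#' @param feature_genes character vector of namespaced feature-gene IDs.
#' @param degs character vector of namespaced DEG IDs.
#' @return named list (`mrna`, `mirna`, `lncrna`) of intersected IDs.
#' @export
defg_intersect <- function(feature_genes, degs) {
  common <- intersect(feature_genes, degs)
  if (length(common) == 0) warning("feature genes and DEGs are disjoint")
  out <- lapply(c(mrna = "mrna:", mirna = "mirna:", lncrna = "lncrna:"),
                function(pre) common[startsWith(common, pre)])
  out
}
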