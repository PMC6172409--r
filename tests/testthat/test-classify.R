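# deterministic stub backends exercising the protocol without a real learner
stub_constant <- function(value = 0.7) {
  list(fit = function(x, y) list(levels = levels(as.factor(y))),
       score = function(model, x) rep(value, nrow(x)),
       importance = function(model) NULL)
}
stub_importance <- function(w) {
  list(fit = function(x, y) list(w = w),
       score = function(model, x) rep(0.5, nrow(x)),
       importance = function(model) model$w)
}

sep_data <- function(n = 60, p = 20, gap = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), each = n / 2))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("S", 1:n), paste0("f", 1:p)))
  x[y == "B", 1:5] <- x[y == "B", 1:5] + gap
  list(x = x, y = y)
}

test_that("stratified split preserves class proportions by largest remainder", {
  samples <- paste0("S", 1:100)
  labels <- rep(c("A", "B"), each = 50)
  sp <- stratified_split(samples, labels, 0.6, seed = 1)
  expect_equal(sum(labels[match(sp$train, samples)] == "A"), 30)
  expect_equal(sum(labels[match(sp$train, samples)] == "B"), 30)
  expect_equal(length(sp$test), 40)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), samples)
  expect_error(stratified_split(samples, labels, 1), "strictly between")
  sp2 <- stratified_split(samples, labels, 0.6, seed = 2)
  expect_false(setequal(sp$train, sp2$train))
  expect_equal(length(sp2$train), length(sp$train))
})

test_that("stratified split stays disjoint and exhaustive across settings", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    labels <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.3, 0.7))
    if (min(table(labels)) < 2) next
    samples <- paste0("S", seq_len(n))
    frac <- runif(1, 0.3, 0.8)
    sp <- stratified_split(samples, labels, frac, seed = i)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), samples)
    expect_equal(length(sp$train), round(frac * n))
  }
})

test_that("cross-validation separates separable data and not shuffled labels", {
  d <- sep_data()
  cv <- cross_validate(backend_logistic(), d$x, d$y, folds = 10, seed = 5)
  expect_gte(cv$mean_accuracy, 0.95)
  set.seed(6)
  cv_null <- cross_validate(backend_logistic(), d$x, sample(d$y), folds = 10,
                            seed = 7)
  expect_lt(abs(cv_null$mean_accuracy - 0.5), 0.15)
  # constant-score backend always predicts class 2
  cv_const <- cross_validate(stub_constant(0.7), d$x, d$y, folds = 5,
                             seed = 8)
  expect_equal(cv_const$mean_accuracy, 0.5)  # balanced classes
})

test_that("ROC/AUC matches closed forms and brute-force pair counting", {
  perfect <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$tpr[nrow(perfect$roc)], 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.3, 0.8), c(TRUE, TRUE, FALSE))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(9)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) next
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(s, pos)$auc, auc_pairs(s, pos), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(10)
  s <- runif(40); pos <- runif(40) > 0.5
  a0 <- roc_auc(s, pos)$auc
  expect_equal(roc_auc(qlogis(s), pos)$auc, a0)
  expect_equal(roc_auc(s^3 + 2 * s, pos)$auc, a0)
})

test_that("AUC agrees with pROC on a generic instance", {
  skip_if_not_installed("pROC")
  set.seed(14)
  s <- runif(60); pos <- runif(60) > 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, pos)$auc, ref, tolerance = 1e-12)
})

test_that("feature ranking follows importance with ID tie-breaks", {
  be <- stub_importance(c(f1 = 0.5, f2 = 0, f3 = 0.2))
  model <- be$fit(NULL, factor(c("A", "B")))
  expect_equal(select_feature_genes(be, model), c("f1", "f3"))
  be0 <- stub_importance(c(f1 = 0, f2 = 0))
  expect_warning(out <- select_feature_genes(be0, be0$fit(NULL, NULL)),
                 "zero")
  expect_length(out, 0)
  # ties broken by ID
  bet <- stub_importance(c(b = 1, a = 1, c = 2))
  expect_equal(select_feature_genes(bet, bet$fit(NULL, NULL)),
               c("c", "a", "b"))
})

test_that("planted discriminative genes surface in the importance ranking", {
  d <- sep_data(n = 50, p = 30, gap = 3, seed = 11)
  be <- backend_logistic()
  model <- be$fit(d$x, d$y)
  top10 <- select_feature_genes(be, model)[1:10]
  expect_gte(length(intersect(paste0("f", 1:5), top10)), 4)
})

test_that("DEFG intersection partitions by layer", {
  feats <- c("mrna:A", "mrna:B", "mirna:X", "lncrna:L1", "lncrna:L2")
  degs <- c("mrna:B", "mrna:C", "mirna:X", "lncrna:L2")
  out <- defg_intersect(feats, degs)
  expect_equal(out$mrna, "mrna:B")
  expect_equal(out$mirna, "mirna:X")
  expect_equal(out$lncrna, "lncrna:L2")
  expect_warning(defg_intersect(c("mrna:A"), c("mrna:B")), "disjoint")
})

test_that("the evaluation protocol runs with a gradient-boosted backend", {
  skip_if_not_installed("xgboost")
  d <- sep_data(n = 40, p = 10, gap = 3, seed = 12)
  be <- backend_xgboost(nrounds = 30, max_depth = 3)
  sp <- stratified_split(rownames(d$x), d$y, 0.6, seed = 13)
  model <- be$fit(d$x[sp$train, ], d$y[match(sp$train, rownames(d$x))])
  sc <- be$score(model, d$x[sp$test, ])
  expect_true(all(sc >= 0 & sc <= 1))
  auc <- roc_auc(sc, d$y[match(sp$test, rownames(d$x))])$auc
  expect_gte(auc, 0.9)
  expect_gte(length(select_feature_genes(be, model)), 1)
})
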