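sep_table <- function(n = 200, seed = 2) {
  # linearly separable: label = indicator(rank_score > median)
  set.seed(seed)
  tab <- data.frame(age = round(rnorm(n, 70, 10)), sex = rbinom(n, 1, .5),
                    node_score = runif(n), edge_score = runif(n),
                    rank_score = runif(n))
  tab$label <- as.integer(tab$rank_score > median(tab$rank_score))
  tab
}

model_formula <- label ~ age + sex + node_score + edge_score + rank_score

test_that("out-of-fold meta-features cover every row exactly once", {
  tab <- sep_table(100)
  X <- as.matrix(tab[, 1:5]); y <- tab$label
  set.seed(1)
  learners <- default_base_learners()
  oof <- oof_meta_features(X, y, learners, n_folds = 5)
  expect_equal(dim(oof$meta), c(100L, 3L))
  expect_false(anyNA(oof$meta))
  expect_equal(colnames(oof$meta), c("oof_dt", "oof_xgb", "oof_lgb"))
  # folds stratified by label and identical across learners (single fold_map)
  expect_equal(sort(unique(oof$fold_map)), 1:5)
  for (f in 1:5)
    expect_gt(min(table(y[oof$fold_map == f])), 0)
})

test_that("a constant stub learner yields a constant meta column", {
  tab <- sep_table(60)
  X <- as.matrix(tab[, 1:5]); y <- tab$label
  set.seed(3)
  learners <- list(stub = learner_constant(0.7),
                   dt = learner_decision_tree())
  oof <- oof_meta_features(X, y, learners, n_folds = 5)
  expect_equal(unname(oof$meta[, "oof_stub"]), rep(0.7, 60))
})

test_that("OOF values come from models that never saw the row", {
  # a memorising stub records the row ids it was trained on (the 'age'
  # column carries a unique id); any leak into its own fold is detectable
  mem <- new_learner(
    name = "mem",
    fit = function(X, y, params) list(ids = X[, "age"]),
    predict_prob = function(model, X) rep(0.5, nrow(X)),
    importance = function(model, feature_names) NULL,
    grid = list(list()))
  tab <- sep_table(80)
  tab$age <- seq_len(nrow(tab))
  X <- as.matrix(tab[, 1:5]); y <- tab$label
  set.seed(9)
  oof <- oof_meta_features(X, y, list(mem = mem), n_folds = 5,
                           smote = FALSE)
  for (f in 1:5) {
    held_ids <- X[oof$fold_map == f, "age"]
    trained_ids <- oof$fold_models[[1]][[f]]$ids
    expect_length(intersect(held_ids, trained_ids), 0L)
    expect_setequal(c(held_ids, trained_ids), X[, "age"])
  }
})

test_that("test meta-features average the five fold predictions", {
  # learner whose fitted model is just a stored constant
  passthrough <- new_learner(
    name = "pass", fit = function(X, y, params) NA_real_,
    predict_prob = function(model, X) rep(model, nrow(X)),
    importance = function(model, feature_names) NULL,
    grid = list(list()))
  fold_models <- list(pass = list(0.2, 0.4, 0.6, 0.8, 1.0))
  X <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  meta <- test_meta_features(X, fold_models, list(pass = passthrough))
  expect_equal(dim(meta), c(3L, 1L))
  expect_equal(unname(meta[, 1]), rep(0.6, 3))

  identical_models <- list(pass = rep(list(0.35), 5))
  meta2 <- test_meta_features(X, identical_models, list(pass = passthrough))
  expect_equal(unname(meta2[, 1]), rep(0.35, 3))

  expect_error(test_meta_features(X, list(), list(pass = passthrough)),
               "differ in length")
})

test_that("crucial-feature selection deduplicates stably", {
  fn <- c("age", "sex", "node_score", "edge_score", "rank_score")
  imp <- function(best) {
    v <- setNames(rep(0, 5), fn); v[best] <- 1; v
  }
  expect_equal(select_crucial_features(
    list(a = imp("rank_score"), b = imp("rank_score"), c = imp("rank_score")),
    fn), "rank_score")
  expect_equal(select_crucial_features(
    list(a = imp("rank_score"), b = imp("edge_score"), c = imp("rank_score")),
    fn), c("rank_score", "edge_score"))
  expect_equal(select_crucial_features(list(a = imp("age")), fn, k = 0),
               character(0))
  expect_error(select_crucial_features(list(a = NULL), fn), "importance")
  # ties broken by fixed feature order
  flat <- setNames(rep(1, 5), fn)
  expect_equal(select_crucial_features(list(a = flat), fn), "age")
})

test_that("SMOTE balances classes without touching original rows", {
  set.seed(4)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- c(rep(1, 15), rep(0, 45))
  bal <- smote_balance(X, y, k = 5)
  expect_equal(sum(bal$y == 1), sum(bal$y == 0))
  expect_equal(bal$X[1:60, ], X)        # originals first, untouched
  expect_equal(bal$y[1:60], y)
  # synthetic rows interpolate minority rows: inside the minority bbox
  syn <- bal$X[-(1:60), , drop = FALSE]
  Xm <- X[y == 1, ]
  for (j in 1:3) {
    expect_gte(min(syn[, j]), min(Xm[, j]) - 1e-12)
    expect_lte(max(syn[, j]), max(Xm[, j]) + 1e-12)
  }
  expect_error(smote_balance(X, rep(1, 60)), "both classes")
  even <- smote_balance(X[1:30, ], rep(c(0, 1), 15))
  expect_equal(nrow(even$X), 30L)
})

test_that("DXLR separates a separable table and is reproducible", {
  tab <- sep_table(200)
  fit <- dxlr(model_formula, tab, seed = 11)
  p <- predict(fit, tab)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auc_score(tab$label, p), 0.99)
  # meta learner sees one OOF column per base learner plus crucial features
  expect_equal(rownames(fit$meta_model$importance),
               c(colnames(fit$oof), fit$crucial_features))
  expect_equal(ncol(fit$oof), 3L)
  expect_gte(length(fit$crucial_features), 1L)
  # reproducibility end to end
  fit2 <- dxlr(model_formula, tab, seed = 11)
  expect_identical(predict(fit, tab), predict(fit2, tab))
  # identical rows get identical probabilities
  dup <- tab[c(1, 1), ]
  expect_equal(predict(fit, dup)[1], predict(fit, dup)[2])
})

test_that("DXLR validates inputs and honours the smote flag", {
  tab <- sep_table(80)
  expect_error(dxlr(model_formula, transform(tab, label = 1)), "single class")
  fit <- dxlr(model_formula, tab, smote = FALSE, seed = 5)
  expect_s3_class(fit, "dxlr")
  missing_col <- tab[, setdiff(names(tab), "rank_score")]
  expect_error(predict(fit, missing_col), "rank_score")
  s <- summary(fit)
  expect_true(all(s$oof_auc > 0.5))
  expect_output(print(fit), "DXLR")
})

test_that("grid search picks parameters by cross-validated AUC", {
  tab <- sep_table(120, seed = 6)
  X <- as.matrix(tab[, 1:5]); y <- tab$label
  learner <- learner_decision_tree(grid = list(
    list(cp = 0.005, maxdepth = 6), list(cp = 0.5, maxdepth = 1)))
  set.seed(2)
  tuned <- tune_learner(learner, X, y, cv_folds = 5, smote = FALSE)
  expect_length(tuned$cv_auc, 2L)
  expect_equal(tuned$params, learner$grid[[which.max(tuned$cv_auc)]])
  # single-point grids skip the search
  quick <- tune_learner(learner_xgboost(), X, y)
  expect_true(is.na(quick$cv_auc))
})

test_that("baseline classifiers emit calibrated probabilities", {
  tab <- sep_table(150, seed = 8)
  fits <- fit_baselines(model_formula, tab, seed = 13)
  expect_named(fits, baseline_model_names())
  for (nm in names(fits)) {
    p <- predict(fits[[nm]], tab)
    expect_true(all(p >= 0 & p <= 1), info = nm)
    expect_length(p, nrow(tab))
  }
  # tree models nail the separable table in-sample
  for (nm in c("dt", "rf", "xgboost", "leafwise_gbm"))
    expect_gt(auc_score(tab$label, predict(fits[[nm]], tab)), 0.99)
  # standardisation parameters come from the training data only
  lr <- fits$lr
  expect_equal(unname(lr$model$std$center),
               unname(colMeans(as.matrix(tab[, 1:5]))))
  expect_error(fit_baseline("nope", model_formula, tab), "unknown baseline")
})
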