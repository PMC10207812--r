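#' Cross-validated hyperparameter search for one learner
#'
#' Evaluates every parameter set in the learner's grid by stratified
#' k-fold cross-validation (AUC of the held-out fold predictions, averaged
#' over folds) and returns the best set. With SMOTE enabled the training
#' folds are rebalanced before each fit; validation folds are never
#' resampled. A single-point grid is returned directly without fitting.
#'
#' @param learner An `hfnet_learner`.
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param cv_folds Number of folds (default 10).
#' @param smote Apply SMOTE inside training folds (default TRUE).
#' @param smote_k SMOTE neighbour count.
#' @return List with `params` (best set) and `cv_auc` (numeric vector over
#'   the grid, NA for a single-point grid).
#' @export
tune_learner <- function(learner, X, y, cv_folds = 10L, smote = TRUE,
                         smote_k = 5L) {
  grid <- learner$grid
  if (length(grid) <= 1L)
    return(list(params = grid[[1L]], cv_auc = NA_real_))
  folds <- stratified_folds(y, cv_folds)
  scores <- vapply(grid, function(params) {
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (smote) {
        bal <- smote_balance(Xtr, ytr, k = smote_k)
        Xtr <- bal$X; ytr <- bal$y
      }
      model <- learner$fit(Xtr, ytr, params)
      auc_score(y[!tr], learner$predict_prob(model, X[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  list(params = grid[[which.max(scores)]], cv_auc = scores)
}

#' Out-of-fold meta-features for the stacking stage
#'
#' Stratified `n_folds`-fold cross-validation, identical folds for every
#' base learner: each learner is fitted on the training folds (SMOTE'd when
#' requested) and predicts the held-out fold, so every training row
#' receives exactly one out-of-fold probability per learner -- a prediction
#' from a model that never saw the row.
#'
#' @param X Numeric feature matrix of the training partition.
#' @param y Binary labels.
#' @param learners Named list of `hfnet_learner`s with chosen `params`
#'   attached as the `params` element of each list entry (see
#'   [dxlr()]), or plain learners (their first grid point is used).
#' @param n_folds Number of out-of-fold folds (default 5).
#' @param smote,smote_k SMOTE settings for the training folds.
#' @return List: `meta` (n x n_learners matrix of OOF probabilities, one
#'   column per learner), `fold_models` (per learner, the `n_folds` fitted
#'   fold models), `fold_map` (fold id per row).
#' @export
oof_meta_features <- function(X, y, learners, n_folds = 5L, smote = TRUE,
                              smote_k = 5L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  params_of <- function(l) if (!is.null(l$params)) l$params else l$grid[[1L]]
  folds <- stratified_folds(y, n_folds)
  meta <- matrix(NA_real_, nrow(X), length(learners),
                 dimnames = list(NULL, paste0("oof_", names(learners))))
  fold_models <- lapply(learners, function(l) vector("list", n_folds))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (smote) {
      bal <- smote_balance(Xtr, ytr, k = smote_k)
      Xtr <- bal$X; ytr <- bal$y
    }
    for (b in seq_along(learners)) {
      l <- learners[[b]]
      model <- l$fit(Xtr, ytr, params_of(l))
      fold_models[[b]][[f]] <- model
      meta[!tr, b] <- l$predict_prob(model, X[!tr, , drop = FALSE])
    }
  }
  if (anyNA(meta)) stop("internal error: incomplete out-of-fold coverage")
  list(meta = meta, fold_models = fold_models, fold_map = folds)
}

#' Meta-features for new data from the fold models
#'
#' Each new row's meta-feature for a base learner is the arithmetic mean of
#' the predictions of that learner's `n_folds` fold models.
#'
#' @param X Numeric feature matrix of new rows.
#' @param fold_models Per-learner list of fold models (from
#'   [oof_meta_features()]).
#' @param learners The matching named list of learners.
#' @return n x n_learners matrix of averaged probabilities.
#' @export
test_meta_features <- function(X, fold_models, learners) {
  if (length(fold_models) != length(learners))
    stop("fold_models and learners differ in length")
  meta <- matrix(NA_real_, nrow(X), length(learners),
                 dimnames = list(NULL, paste0("oof_", names(learners))))
  for (b in seq_along(learners)) {
    preds <- vapply(fold_models[[b]],
                    function(m) learners[[b]]$predict_prob(m, X),
                    numeric(nrow(X)))
    meta[, b] <- if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
  }
  meta
}

#' Select each base learner's most important features
#'
#' Takes the top `k` features of every base learner by its own importance
#' measure (impurity/gain based for the tree learners), breaking ties by
#' the fixed feature order, and returns the deduplicated union in
#' first-seen order. These "crucial features" join the out-of-fold columns
#' in the meta learner's input.
#'
#' @param importances Named list of per-learner importance vectors (each
#'   named by feature).
#' @param feature_names Fixed feature order.
#' @param k Features per learner (default 1; 0 gives an empty selection).
#' @return Character vector of selected feature names.
#' @export
select_crucial_features <- function(importances, feature_names, k = 1L) {
  if (k == 0L) return(character(0))
  out <- character(0)
  for (nm in names(importances)) {
    imp <- importances[[nm]]
    if (is.null(imp))
      stop(sprintf("base learner '%s' exposes no feature importance", nm))
    imp <- imp[feature_names]  # fixed order; order() breaks ties by position
    top <- feature_names[order(-imp)][seq_len(min(k, length(feature_names)))]
    out <- c(out, setdiff(top, out))
  }
  out
}

#' Fit the DXLR two-stage stacking ensemble
#'
#' Stage 1: each base learner (by default a decision tree, gradient-boosted
#' trees, and leaf-wise gradient-boosted trees) is tuned by cross-validated
#' grid search, then produces out-of-fold probabilities via stratified
#' `n_folds`-fold cross-validation (SMOTE rebalancing applied to the
#' training folds only). Stage 2: the most important feature of each base
#' learner ("crucial features") is appended to the out-of-fold columns and
#' a random-forest meta learner is fitted on the combined matrix. Base
#' learners are also refitted on the full (rebalanced) training partition;
#' these full fits supply the feature importances.
#'
#' Predictions for new data average each base learner's fold models into
#' meta-features and feed them, plus the crucial feature columns, to the
#' meta learner.
#'
#' @param formula Model formula, e.g.
#'   `label ~ age + sex + node_score + edge_score + rank_score`.
#' @param data Data frame containing the response (binary 0/1) and
#'   features.
#' @param base_learners Named list of `hfnet_learner`s (default
#'   [default_base_learners()]).
#' @param n_folds Out-of-fold folds for stage 1 (default 5).
#' @param crucial_k Features per base learner merged as crucial features
#'   (default 1).
#' @param smote Rebalance stage-1 training folds with SMOTE (default TRUE).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param meta_ntree Trees in the random-forest meta learner (default 300).
#' @param cv_folds Folds for the hyperparameter grid search (default 10).
#' @param seed Integer seed; fitting and prediction are reproducible given
#'   the seed.
#' @return An object of class `dxlr`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(age = rnorm(120, 70, 10), sex = rbinom(120, 1, .5),
#'                 node_score = runif(120), edge_score = runif(120),
#'                 rank_score = runif(120))
#' d$label <- as.integer(d$rank_score > stats::median(d$rank_score))
#' fit <- dxlr(label ~ age + sex + node_score + edge_score + rank_score,
#'             d, seed = 7)
#' head(predict(fit, d))
dxlr <- function(formula, data, base_learners = default_base_learners(),
                 n_folds = 5L, crucial_k = 1L, smote = TRUE, smote_k = 5L,
                 meta_ntree = 300L, cv_folds = 10L, seed = 1L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("training data contain a single class")
  feature_names <- attr(stats::terms(mf), "term.labels")
  X <- feature_matrix(mf, feature_names)
  if (is.null(names(base_learners)) || any(names(base_learners) == ""))
    stop("base_learners must be a named list")

  set.seed(seed)
  # stage 0: grid search per base learner (10-fold CV, AUC)
  for (b in seq_along(base_learners)) {
    tuned <- tune_learner(base_learners[[b]], X, y, cv_folds = cv_folds,
                          smote = smote, smote_k = smote_k)
    base_learners[[b]]$params <- tuned$params
    base_learners[[b]]$cv_auc <- tuned$cv_auc
  }
  # stage 1: out-of-fold meta-features
  oof <- oof_meta_features(X, y, base_learners, n_folds = n_folds,
                           smote = smote, smote_k = smote_k)
  # full-training refits supply importances (and the deployment models)
  Xfull <- X; yfull <- y
  if (smote) {
    bal <- smote_balance(X, y, k = smote_k)
    Xfull <- bal$X; yfull <- bal$y
  }
  full_models <- lapply(base_learners,
                        function(l) l$fit(Xfull, yfull, l$params))
  importances <- lapply(seq_along(base_learners), function(b)
    base_learners[[b]]$importance(full_models[[b]], feature_names))
  names(importances) <- names(base_learners)
  crucial <- select_crucial_features(importances, feature_names,
                                     k = crucial_k)
  # stage 2: random-forest meta learner on [OOF columns ++ crucial features]
  meta_X <- cbind(oof$meta, X[, crucial, drop = FALSE])
  meta_model <- randomForest::randomForest(
    x = as_model_frame(meta_X), y = factor(y, levels = c(0, 1)),
    ntree = meta_ntree)

  structure(list(call = cl, formula = formula,
                 feature_names = feature_names,
                 learners = base_learners,
                 fold_models = oof$fold_models,
                 fold_map = oof$fold_map,
                 oof = oof$meta,
                 full_models = full_models,
                 importances = importances,
                 crucial_features = crucial,
                 meta_model = meta_model,
                 y = y, n = nrow(X),
                 smote = smote, smote_k = smote_k,
                 n_folds = n_folds, seed = seed),
            class = "dxlr")
}

dxlr_meta_matrix <- function(object, X) {
  meta <- test_meta_features(X, object$fold_models, object$learners)
  cbind(meta, X[, object$crucial_features, drop = FALSE])
}

#' Predict heart-failure risk with a fitted DXLR stack
#'
#' @param object A fitted [dxlr()] model.
#' @param newdata Data frame with the model's feature columns.
#' @param type `"prob"` (default) for P(case), `"class"` for a 0/1 call at
#'   `threshold`.
#' @param threshold Classification threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric probability vector, or integer class vector.
#' @export
predict.dxlr <- function(object, newdata, type = c("prob", "class"),
                         threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata, object$feature_names)
  meta_X <- dxlr_meta_matrix(object, X)
  p <- unname(stats::predict(object$meta_model, as_model_frame(meta_X),
                             type = "prob")[, "1"])
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
print.dxlr <- function(x, ...) {
  cat("DXLR two-stage stacking ensemble\n")
  cat(sprintf("  trained on %d patients (%d cases, %d controls)%s\n",
              x$n, sum(x$y == 1L), sum(x$y == 0L),
              if (x$smote) ", SMOTE-balanced folds" else ""))
  cat(sprintf("  base learners: %s (%d-fold OOF stacking)\n",
              paste(vapply(x$learners, `[[`, "", "name"), collapse = ", "),
              x$n_folds))
  cat(sprintf("  crucial features: %s\n",
              paste(x$crucial_features, collapse = ", ")))
  cat(sprintf("  meta learner: random forest (%d trees)\n",
              x$meta_model$ntree))
  invisible(x)
}

#' Summarise a fitted DXLR stack
#'
#' Reports the out-of-fold AUC of each base learner on the training
#' partition, the selected crucial features, and each base learner's
#' feature importances.
#'
#' @param object A fitted [dxlr()] model.
#' @param ... Unused.
#' @return An object of class `summary.dxlr`.
#' @export
summary.dxlr <- function(object, ...) {
  oof_auc <- vapply(seq_len(ncol(object$oof)), function(b)
    auc_score(object$y, object$oof[, b]), numeric(1))
  names(oof_auc) <- colnames(object$oof)
  structure(list(model = object, oof_auc = oof_auc),
            class = "summary.dxlr")
}

#' @export
print.summary.dxlr <- function(x, ...) {
  print(x$model)
  cat("\nOut-of-fold AUC of base learners (training partition):\n")
  print(round(x$oof_auc, 4))
  cat("\nBase-learner feature importances:\n")
  imp <- do.call(cbind, x$model$importances)
  print(round(imp, 4))
  invisible(x)
}

#' Plot base-learner feature importances of a DXLR stack
#'
#' Grouped bar chart of each base learner's (column-normalised) feature
#' importances; crucial features are marked with an asterisk.
#'
#' @param x A fitted [dxlr()] model.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.dxlr <- function(x, ...) {
  imp <- do.call(cbind, x$importances)
  norm <- sweep(imp, 2L, pmax(colSums(imp), .Machine$double.eps), "/")
  labs <- rownames(norm)
  labs[labs %in% x$crucial_features] <-
    paste0(labs[labs %in% x$crucial_features], "*")
  graphics::barplot(t(norm), beside = TRUE, names.arg = labs,
                    legend.text = colnames(norm),
                    ylab = "normalised importance",
                    main = "DXLR base-learner feature importance", ...)
  invisible(x)
}
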