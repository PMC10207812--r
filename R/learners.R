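#' Define a custom learner
#'
#' Learners are the pluggable unit of the stacking and evaluation
#' machinery: a name, a `fit(X, y, params)` function returning a fitted
#' model (X a numeric matrix, y binary 0/1), a `predict_prob(model, X)`
#' function returning P(y = 1), an `importance(model, feature_names)`
#' function returning a named numeric vector (or NULL when the learner
#' exposes none), and a hyperparameter `grid` (list of candidate parameter
#' lists; a single-point grid fixes the parameters).
#'
#' @param name Display name.
#' @param fit,predict_prob,importance Functions as described above.
#' @param grid List of named parameter lists.
#' @return An object of class `hfnet_learner`.
#' @export
new_learner <- function(name, fit, predict_prob, importance, grid) {
  structure(list(name = name, fit = fit, predict_prob = predict_prob,
                 importance = importance, grid = grid),
            class = "hfnet_learner")
}

#' @export
print.hfnet_learner <- function(x, ...) {
  cat(sprintf("Learner '%s' (%d-point grid)\n", x$name, length(x$grid)))
  invisible(x)
}

as_model_frame <- function(X) {
  df <- as.data.frame(X)
  names(df) <- colnames(X)
  df
}

#' Built-in learners
#'
#' Constructors for the learners used by the DXLR ensemble and the baseline
#' comparison: a CART decision tree (`rpart`), depth-wise gradient-boosted
#' trees (`xgboost`), leaf-wise (best-first) gradient-boosted trees
#' (xgboost with `grow_policy = "lossguide"`, the LightGBM-style growth
#' strategy), a random forest, L2 logistic regression and a linear-kernel
#' SVM with Platt-calibrated probabilities. The linear models standardise
#' their inputs with training-set parameters. `learner_constant()` always
#' predicts a fixed probability and exists to test the stacking plumbing.
#'
#' Each learner carries a hyperparameter `grid`: a list of candidate
#' parameter sets searched by cross-validated AUC when longer than one.
#'
#' @param grid Optional replacement grid (list of named parameter lists).
#' @param p Constant probability for `learner_constant()`.
#' @return An object of class `hfnet_learner`.
#' @name learners
NULL

#' @rdname learners
#' @export
learner_decision_tree <- function(grid = list(list(cp = 0.005, maxdepth = 6))) {
  new_learner(
    name = "decision_tree",
    fit = function(X, y, params) {
      df <- as_model_frame(X)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp,
                                                  maxdepth = params$maxdepth,
                                                  xval = 0))
    },
    predict_prob = function(model, X) {
      unname(stats::predict(model, as_model_frame(X), type = "prob")[, "1"])
    },
    importance = function(model, feature_names) {
      imp <- stats::setNames(numeric(length(feature_names)), feature_names)
      vi <- model$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- vi
      imp
    },
    grid = grid)
}

xgb_fit <- function(X, y, params, extra) {
  storage.mode(X) <- "double"
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = 1,
                    eta = params$eta), extra(params)),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

xgb_predict <- function(model, X) {
  storage.mode(X) <- "double"
  as.numeric(stats::predict(model, X))
}

xgb_importance <- function(model, feature_names) {
  imp <- stats::setNames(numeric(length(feature_names)), feature_names)
  tab <- tryCatch(xgboost::xgb.importance(model = model), error = function(e) NULL)
  if (!is.null(tab) && nrow(tab)) {
    found <- intersect(tab$Feature, feature_names)
    imp[found] <- tab$Gain[match(found, tab$Feature)]
  }
  imp
}

#' @rdname learners
#' @export
learner_xgboost <- function(grid = list(list(eta = 0.1, max_depth = 4,
                                             nrounds = 120))) {
  new_learner(
    name = "xgboost",
    fit = function(X, y, params)
      xgb_fit(X, y, params, function(p) list(max_depth = p$max_depth)),
    predict_prob = xgb_predict,
    importance = xgb_importance,
    grid = grid)
}

#' @rdname learners
#' @export
learner_leafwise_gbm <- function(grid = list(list(eta = 0.1, max_leaves = 15,
                                                  nrounds = 120))) {
  new_learner(
    name = "leafwise_gbm",
    fit = function(X, y, params)
      xgb_fit(X, y, params,
              function(p) list(grow_policy = "lossguide", max_depth = 0,
                               max_leaves = p$max_leaves,
                               tree_method = "hist")),
    predict_prob = xgb_predict,
    importance = xgb_importance,
    grid = grid)
}

#' @rdname learners
#' @export
learner_random_forest <- function(grid = list(list(ntree = 300))) {
  new_learner(
    name = "random_forest",
    fit = function(X, y, params) {
      randomForest::randomForest(x = as_model_frame(X),
                                 y = factor(y, levels = c(0, 1)),
                                 ntree = params$ntree)
    },
    predict_prob = function(model, X) {
      unname(stats::predict(model, as_model_frame(X), type = "prob")[, "1"])
    },
    importance = function(model, feature_names) {
      imp <- stats::setNames(numeric(length(feature_names)), feature_names)
      vi <- randomForest::importance(model)[, 1L]
      imp[names(vi)] <- vi
      imp
    },
    grid = grid)
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl,
       apply = function(Z) sweep(sweep(Z, 2L, ctr), 2L, scl, "/"))
}

#' @rdname learners
#' @export
learner_logistic <- function(grid = list(list())) {
  new_learner(
    name = "logistic",
    fit = function(X, y, params) {
      std <- standardizer(X)
      df <- as_model_frame(std$apply(X))
      df$.y <- y
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial()))
      list(glm = fit, std = std)
    },
    predict_prob = function(model, X) {
      unname(stats::predict(model$glm, as_model_frame(model$std$apply(X)),
                            type = "response"))
    },
    importance = function(model, feature_names) {
      co <- stats::coef(model$glm)[-1L]
      imp <- stats::setNames(numeric(length(feature_names)), feature_names)
      imp[names(co)] <- abs(co)
      imp
    },
    grid = grid)
}

#' @rdname learners
#' @export
learner_svm_linear <- function(grid = list(list(cost = 1))) {
  new_learner(
    name = "svm_linear",
    fit = function(X, y, params) {
      std <- standardizer(X)
      fit <- e1071::svm(x = std$apply(X), y = factor(y, levels = c(0, 1)),
                        kernel = "linear", cost = params$cost,
                        probability = TRUE, scale = FALSE)
      list(svm = fit, std = std)
    },
    predict_prob = function(model, X) {
      pred <- stats::predict(model$svm, model$std$apply(X), probability = TRUE)
      unname(attr(pred, "probabilities")[, "1"])
    },
    importance = function(model, feature_names) NULL,
    grid = grid)
}

#' @rdname learners
#' @export
learner_constant <- function(p = 0.5) {
  new_learner(
    name = sprintf("constant_%g", p),
    fit = function(X, y, params) p,
    predict_prob = function(model, X) rep(model, nrow(X)),
    importance = function(model, feature_names)
      stats::setNames(numeric(length(feature_names)), feature_names),
    grid = list(list()))
}

#' Default DXLR base learners
#'
#' The three base learners of the DXLR stack: decision tree, gradient
#' boosting and leaf-wise gradient boosting.
#'
#' @return Named list of `hfnet_learner` objects.
#' @export
default_base_learners <- function() {
  list(dt = learner_decision_tree(),
       xgb = learner_xgboost(),
       lgb = learner_leafwise_gbm())
}
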