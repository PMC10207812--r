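baseline_constructors <- function() {
  list(lr = learner_logistic,
       svm = learner_svm_linear,
       dt = learner_decision_tree,
       rf = learner_random_forest,
       xgboost = learner_xgboost,
       leafwise_gbm = learner_leafwise_gbm)
}

#' Names of the built-in baseline classifiers
#'
#' @return Character vector: logistic regression (`lr`), linear-kernel SVM
#'   (`svm`), decision tree (`dt`), random forest (`rf`), gradient boosting
#'   (`xgboost`) and leaf-wise gradient boosting (`leafwise_gbm`).
#' @export
baseline_model_names <- function() names(baseline_constructors())

#' Fit one baseline classifier
#'
#' Tunes the learner by cross-validated grid search (when its grid has more
#' than one point), applies SMOTE to the training data when requested, and
#' fits. The linear models (logistic regression, linear SVM) standardise
#' inputs with training-set parameters internally.
#'
#' @param model One of [baseline_model_names()], or an `hfnet_learner`.
#' @param formula Model formula (binary response).
#' @param data Training data frame.
#' @param smote,smote_k SMOTE settings.
#' @param cv_folds Grid-search folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `hfnet_baseline` with a `predict()` method
#'   returning probabilities.
#' @export
fit_baseline <- function(model, formula, data, smote = TRUE, smote_k = 5L,
                         cv_folds = 10L, seed = 1L) {
  learner <- if (inherits(model, "hfnet_learner")) model
  else {
    ctors <- baseline_constructors()
    if (!model %in% names(ctors))
      stop(sprintf("unknown baseline '%s'; available: %s", model,
                   paste(names(ctors), collapse = ", ")))
    ctors[[model]]()
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  feature_names <- attr(stats::terms(mf), "term.labels")
  X <- feature_matrix(mf, feature_names)
  set.seed(seed)
  tuned <- tune_learner(learner, X, y, cv_folds = cv_folds, smote = smote,
                        smote_k = smote_k)
  Xtr <- X; ytr <- y
  if (smote) {
    bal <- smote_balance(X, y, k = smote_k)
    Xtr <- bal$X; ytr <- bal$y
  }
  fit <- learner$fit(Xtr, ytr, tuned$params)
  structure(list(learner = learner, model = fit, params = tuned$params,
                 cv_auc = tuned$cv_auc, feature_names = feature_names,
                 formula = formula, smote = smote, seed = seed),
            class = "hfnet_baseline")
}

#' Fit the six baseline classifiers
#'
#' @param formula Model formula.
#' @param data Training data frame.
#' @param models Which baselines to fit (default all six).
#' @param ... Passed to [fit_baseline()].
#' @return Named list of `hfnet_baseline` fits.
#' @export
fit_baselines <- function(formula, data, models = baseline_model_names(),
                          ...) {
  fits <- lapply(models, fit_baseline, formula = formula, data = data, ...)
  names(fits) <- models
  fits
}

#' @export
predict.hfnet_baseline <- function(object, newdata,
                                   type = c("prob", "class"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata, object$feature_names)
  p <- object$learner$predict_prob(object$model, X)
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
print.hfnet_baseline <- function(x, ...) {
  cat(sprintf("Baseline classifier '%s' on features: %s\n",
              x$learner$name, paste(x$feature_names, collapse = ", ")))
  invisible(x)
}
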