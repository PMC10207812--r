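default_feature_cols <- function() {
  c("age", "sex", "node_score", "edge_score", "rank_score")
}

fit_any_model <- function(model, formula, data, smote, cv_folds, seed) {
  if (identical(model, "dxlr"))
    dxlr(formula, data, smote = smote, cv_folds = cv_folds, seed = seed)
  else
    fit_baseline(model, formula, data, smote = smote, cv_folds = cv_folds,
                 seed = seed)
}

# Accept either model names ("dxlr", baseline names) or hfnet_learner
# objects; returns a named list.
normalize_models <- function(models) {
  if (!is.list(models)) models <- as.list(models)
  nms <- names(models)
  if (is.null(nms)) nms <- rep("", length(models))
  for (i in seq_along(models)) {
    if (nms[i] == "")
      nms[i] <- if (is.character(models[[i]])) models[[i]]
      else models[[i]]$name
  }
  stats::setNames(models, nms)
}

#' Repeated stratified-split evaluation protocol
#'
#' The outer evaluation loop: `n_repeats` times, the feature table is split
#' into stratified training (`train_frac`, default 80%) and test sets;
#' each model is tuned (cross-validated grid search) and fitted on the
#' training set with SMOTE rebalancing, and its metrics are computed on the
#' untouched test set. Results are reported as mean and standard deviation
#' over the repeats. Per-repeat seeds are derived deterministically from
#' the master seed.
#'
#' @param features Feature table (columns of [build_feature_table()]).
#' @param models Character vector over `"dxlr"` and
#'   [baseline_model_names()].
#' @param n_repeats Number of random splits (>= 2; default 100).
#' @param train_frac Training share per split (default 0.8).
#' @param cv_folds Grid-search folds inside each training set (default 10).
#' @param smote Apply SMOTE to training data (default TRUE).
#' @param threshold Classification threshold (default 0.5).
#' @param seed Master seed.
#' @param feature_cols Feature columns used as model inputs.
#' @param keep_predictions Keep per-repeat test-set predictions (needed by
#'   subgroup analysis).
#' @return An `eval_report`: list with `summary` (model x metric mean/sd
#'   data frame), `per_repeat` (long data frame of per-repeat metrics),
#'   `n_repeats`, and optionally `predictions`.
#' @export
repeated_split_evaluation <- function(features,
                                      models = c("dxlr", baseline_model_names()),
                                      n_repeats = 100L, train_frac = 0.8,
                                      cv_folds = 10L, smote = TRUE,
                                      threshold = 0.5, seed = 1L,
                                      feature_cols = default_feature_cols(),
                                      keep_predictions = FALSE) {
  if (n_repeats < 2L)
    stop("n_repeats must be >= 2 (standard deviations are undefined otherwise)")
  stopifnot(all(feature_cols %in% names(features)),
            "label" %in% names(features))
  models <- normalize_models(models)
  model_names <- names(models)
  formula <- stats::as.formula(
    paste("label ~", paste(feature_cols, collapse = " + ")))
  set.seed(seed)
  repeat_seeds <- draw_seeds(n_repeats)
  rows <- list()
  predictions <- if (keep_predictions) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    in_train <- stratified_split(features$label, train_frac)
    model_seeds <- draw_seeds(length(models))
    train <- features[in_train, , drop = FALSE]
    test <- features[!in_train, , drop = FALSE]
    rep_pred <- if (keep_predictions)
      list(test_index = which(!in_train), probs = list()) else NULL
    for (m in seq_along(models)) {
      fit <- fit_any_model(models[[m]], formula, train, smote = smote,
                           cv_folds = cv_folds, seed = model_seeds[m])
      p <- stats::predict(fit, test)
      met <- suppressWarnings(
        compute_metrics(test$label, p, threshold = threshold))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, model = model_names[m],
        precision = met$precision, recall = met$recall,
        accuracy = met$accuracy, f1 = met$f1, auc = met$auc,
        stringsAsFactors = FALSE)
      if (keep_predictions) rep_pred$probs[[model_names[m]]] <- p
    }
    if (keep_predictions) predictions[[r]] <- rep_pred
  }
  per_repeat <- do.call(rbind, rows)
  metric_names <- c("precision", "recall", "accuracy", "f1", "auc")
  summ <- do.call(rbind, lapply(model_names, function(m) {
    sub <- per_repeat[per_repeat$model == m, , drop = FALSE]
    data.frame(model = m,
               metric = metric_names,
               mean = vapply(metric_names,
                             function(k) mean(sub[[k]], na.rm = TRUE),
                             numeric(1)),
               sd = vapply(metric_names,
                           function(k) stats::sd(sub[[k]], na.rm = TRUE),
                           numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, per_repeat = per_repeat,
                 n_repeats = n_repeats, models = model_names,
                 train_frac = train_frac, threshold = threshold,
                 seed = seed, feature_cols = feature_cols,
                 predictions = predictions),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Repeated-split evaluation: %d repeats, %.0f/%.0f split\n",
              x$n_repeats, 100 * x$train_frac, 100 * (1 - x$train_frac)))
  for (m in x$models) {
    sub <- x$summary[x$summary$model == m, ]
    cat(sprintf("  %-12s %s\n", m,
                paste(sprintf("%s %.3f±%.3f", sub$metric, sub$mean, sub$sd),
                      collapse = "  ")))
  }
  invisible(x)
}

#' Report one metric of one model from an evaluation report
#'
#' @param report An `eval_report`.
#' @param model Model name.
#' @param metric One of `precision`, `recall`, `accuracy`, `f1`, `auc`.
#' @param what `"mean"` or `"sd"`.
#' @return A single number.
#' @export
report_metric <- function(report, model, metric = "auc", what = "mean") {
  s <- report$summary
  s[[what]][s$model == model & s$metric == metric]
}

#' Compare two models' per-repeat metrics with a t-test
#'
#' Paired two-sided t-test over the per-repeat metric values of two models
#' evaluated on the same splits.
#'
#' @param report An `eval_report` containing both models.
#' @param model_a,model_b Model names.
#' @param metric Metric name (default `"auc"`).
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_models <- function(report, model_a, model_b, metric = "auc") {
  pr <- report$per_repeat
  a <- pr[[metric]][pr$model == model_a]
  b <- pr[[metric]][pr$model == model_b]
  stats::t.test(a, b, paired = TRUE)
}

#' Network-feature ablation experiment
#'
#' Re-runs the repeated-split protocol for the full feature set and for
#' each network feature removed in turn (`-Node`, `-Edge`, `-Rank`),
#' quantifying what each similarity score contributes to discrimination.
#'
#' @param features Feature table.
#' @param models Models to evaluate per variant (default `"dxlr"`).
#' @param n_repeats,seed,... Passed to [repeated_split_evaluation()].
#' @return Data frame of per-variant summaries (columns of the report
#'   summary plus `variant`), of class `ablation_report`.
#' @export
ablation_network_features <- function(features, models = "dxlr",
                                      n_repeats = 10L, seed = 1L, ...) {
  variants <- list("full" = character(0),
                   "-Node" = "node_score",
                   "-Edge" = "edge_score",
                   "-Rank" = "rank_score")
  out <- lapply(names(variants), function(v) {
    cols <- setdiff(default_feature_cols(), variants[[v]])
    rep <- repeated_split_evaluation(features, models = models,
                                     n_repeats = n_repeats, seed = seed,
                                     feature_cols = cols, ...)
    cbind(variant = v, rep$summary, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ablation_report", class(res))
  res
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Network-feature ablation (mean ± SD over repeats)\n")
  for (v in unique(x$variant)) {
    sub <- x[x$variant == v & x$metric == "auc", ]
    cat(sprintf("  %-6s AUC %.3f±%.3f\n", v, sub$mean, sub$sd))
  }
  invisible(x)
}

default_age_bins <- function() {
  list(breaks = c(18, 45, 60, 70, 80, Inf),
       labels = c("18-44", "45-59", "60-69", "70-79", "80+"))
}

#' Subgroup (sensitivity) analysis of the repeated-split protocol
#'
#' Models are trained on the full training set of each repeat; only the
#' test-set evaluation is stratified, by sex and by age group (18-44,
#' 45-59, 60-69, 70-79, 80+). Subgroups with a single label class in a
#' repeat are skipped for AUC in that repeat and the skip count reported;
#' empty subgroups are reported as absent. A pooled row is included (the
#' union of subgroups need not reproduce pooled metrics). Sex differences
#' are tested per metric with a two-sample t-test over repeats, age-group
#' differences with one-way ANOVA.
#'
#' @param features Feature table.
#' @param model Model to evaluate (default `"dxlr"`).
#' @param n_repeats,train_frac,cv_folds,smote,threshold,seed As in
#'   [repeated_split_evaluation()].
#' @return List of class `subgroup_report`: `summary` (subgroup x metric
#'   mean/sd with `n_mean` average subgroup size and `auc_skipped` counts),
#'   `tests` (p-values), `per_repeat`.
#' @export
subgroup_analysis <- function(features, model = "dxlr", n_repeats = 10L,
                              train_frac = 0.8, cv_folds = 10L,
                              smote = TRUE, threshold = 0.5, seed = 1L) {
  report <- repeated_split_evaluation(features, models = model,
                                      n_repeats = n_repeats,
                                      train_frac = train_frac,
                                      cv_folds = cv_folds, smote = smote,
                                      threshold = threshold, seed = seed,
                                      keep_predictions = TRUE)
  bins <- default_age_bins()
  rows <- list()
  for (r in seq_len(n_repeats)) {
    pred <- report$predictions[[r]]
    test <- features[pred$test_index, , drop = FALSE]
    p <- pred$probs[[model]]
    groups <- c(list(pooled = rep(TRUE, nrow(test)),
                     male = test$sex == 1L,
                     female = test$sex == 0L),
                lapply(split(seq_len(nrow(test)),
                             cut(test$age, breaks = bins$breaks,
                                 labels = bins$labels, right = FALSE,
                                 include.lowest = TRUE)),
                       function(i) seq_len(nrow(test)) %in% i))
    for (g in names(groups)) {
      sel <- groups[[g]]
      if (!any(sel)) next
      met <- suppressWarnings(
        compute_metrics(test$label[sel], p[sel], threshold = threshold))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, subgroup = g, n = sum(sel),
        precision = met$precision, recall = met$recall,
        accuracy = met$accuracy, f1 = met$f1, auc = met$auc,
        stringsAsFactors = FALSE)
    }
  }
  per_repeat <- do.call(rbind, rows)
  metric_names <- c("precision", "recall", "accuracy", "f1", "auc")
  summ <- do.call(rbind, lapply(unique(per_repeat$subgroup), function(g) {
    sub <- per_repeat[per_repeat$subgroup == g, , drop = FALSE]
    data.frame(subgroup = g,
               metric = metric_names,
               mean = vapply(metric_names,
                             function(k) mean(sub[[k]], na.rm = TRUE),
                             numeric(1)),
               sd = vapply(metric_names,
                           function(k) stats::sd(sub[[k]], na.rm = TRUE),
                           numeric(1)),
               n_mean = mean(sub$n),
               auc_skipped = sum(is.na(sub$auc)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  age_labels <- bins$labels
  tests <- lapply(stats::setNames(metric_names, metric_names), function(k) {
    sex_p <- tryCatch({
      a <- per_repeat[[k]][per_repeat$subgroup == "male"]
      b <- per_repeat[[k]][per_repeat$subgroup == "female"]
      stats::t.test(a, b)$p.value
    }, error = function(e) NA_real_)
    age_sub <- per_repeat[per_repeat$subgroup %in% age_labels &
                            !is.na(per_repeat[[k]]), , drop = FALSE]
    age_p <- tryCatch(
      summary(stats::aov(age_sub[[k]] ~ factor(age_sub$subgroup)))[[1]][
        "factor(age_sub$subgroup)", "Pr(>F)"],
      error = function(e) NA_real_)
    c(sex = sex_p, age = age_p)
  })
  structure(list(summary = summ, per_repeat = per_repeat, tests = tests,
                 model = model, n_repeats = n_repeats),
            class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf("Subgroup analysis of '%s' over %d repeats\n",
              x$model, x$n_repeats))
  for (g in unique(x$summary$subgroup)) {
    sub <- x$summary[x$summary$subgroup == g & x$summary$metric == "auc", ]
    cat(sprintf("  %-8s n≈%.0f  AUC %.3f±%.3f%s\n", g, sub$n_mean,
                sub$mean, sub$sd,
                if (sub$auc_skipped > 0)
                  sprintf(" (AUC skipped in %d repeats)", sub$auc_skipped)
                else ""))
  }
  invisible(x)
}
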