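#' Exact interventional Shapley values for a black-box predictor
#'
#' Computes additive feature attributions by exhaustive coalition
#' enumeration: for every subset S of features, the value function is the
#' prediction averaged over a background sample with the features in S
#' fixed to the explained row's values. Feasible for the small feature
#' spaces used here (at most ~12 features, 2^m coalitions). With a finite
#' background this is exactly additive: per row, the attributions sum to
#' `f(x) - mean(f(background))`.
#'
#' @param f Prediction function: numeric matrix -> numeric vector.
#' @param X Numeric matrix of rows to explain (with column names).
#' @param background Numeric matrix of background rows (same columns).
#' @return List: `phi` (matrix of attributions, `nrow(X)` x features),
#'   `base_value` (mean background prediction).
#' @export
shapley_values <- function(f, X, background) {
  m <- ncol(X)
  if (m > 12L) stop("exact Shapley enumeration limited to 12 features")
  nb <- nrow(background)
  n <- nrow(X)
  n_sets <- 2L^m
  # v[i, s] = value of coalition with bitmask s-1 for row i
  v <- matrix(NA_real_, n, n_sets)
  bg_rep <- background[rep(seq_len(nb), times = n), , drop = FALSE]
  row_rep <- rep(seq_len(n), each = nb)
  for (s in seq_len(n_sets)) {
    mask <- bitwAnd(s - 1L, bitwShiftL(1L, seq_len(m) - 1L)) > 0L
    Z <- bg_rep
    if (any(mask))
      Z[, mask] <- X[row_rep, mask, drop = FALSE]
    pred <- f(Z)
    v[, s] <- rowsum(pred, row_rep)[, 1L] / nb
  }
  # Shapley weights by coalition size
  fact <- factorial(0:m)
  phi <- matrix(0, n, m, dimnames = list(NULL, colnames(X)))
  masks <- lapply(seq_len(n_sets),
                  function(s) bitwAnd(s - 1L, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
  sizes <- vapply(masks, sum, 1L)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (s in seq_len(n_sets)) {
      if (bitwAnd(s - 1L, bit) > 0L) next  # S must exclude i
      sz <- sizes[s]
      w <- fact[sz + 1L] * fact[m - sz] / fact[m + 1L]
      phi[, i] <- phi[, i] + w * (v[, s + bit] - v[, s])
    }
  }
  list(phi = phi, base_value = mean(f(background)))
}

#' Feature attribution summary for a fitted DXLR stack
#'
#' Explains the end-to-end DXLR prediction in terms of the original input
#' features. Shapley values are first computed for the meta learner over
#' its inputs (the out-of-fold columns and the crucial-feature columns);
#' crucial-column attributions map directly to their input features, and
#' each out-of-fold column's attribution is distributed over the input
#' features in proportion to the absolute Shapley attributions of that base
#' learner's own prediction. The signed per-row attributions therefore
#' still sum to `prediction - base value`. Features are summarised by the
#' mean absolute attribution, in decreasing order.
#'
#' @param stack A fitted [dxlr()] model.
#' @param newdata Data frame of rows to explain (test partition).
#' @param background Optional data frame of background rows; default: a
#'   sample of `newdata`.
#' @param n_background Background sample size (default 50).
#' @param max_explain Cap on the number of explained rows (default 200).
#' @param seed Seed for the background/explained-row subsampling.
#' @return List of class `dxlr_attribution`: `summary` (data frame
#'   `feature`, `mean_abs_attribution`, descending), `phi` (per-row
#'   attribution matrix over input features), `base_value`.
#' @export
attribution_summary <- function(stack, newdata, background = NULL,
                                n_background = 50L, max_explain = 200L,
                                seed = 1L) {
  stopifnot(inherits(stack, "dxlr"))
  set.seed(seed)
  X <- feature_matrix(newdata, stack$feature_names)
  if (nrow(X) > max_explain)
    X <- X[sample.int(nrow(X), max_explain), , drop = FALSE]
  Xbg <- if (is.null(background)) {
    if (nrow(X) <= n_background) X
    else X[sample.int(nrow(X), n_background), , drop = FALSE]
  } else {
    B <- feature_matrix(background, stack$feature_names)
    if (nrow(B) > n_background)
      B <- B[sample.int(nrow(B), n_background), , drop = FALSE]
    B
  }

  meta_fun <- function(M) {
    unname(stats::predict(stack$meta_model, as_model_frame(M),
                          type = "prob")[, "1"])
  }
  M <- dxlr_meta_matrix(stack, X)
  Mbg <- dxlr_meta_matrix(stack, Xbg)
  meta_shap <- shapley_values(meta_fun, M, Mbg)

  phi_input <- matrix(0, nrow(X), length(stack$feature_names),
                      dimnames = list(NULL, stack$feature_names))
  # crucial-feature columns map to themselves
  for (cf in stack$crucial_features)
    phi_input[, cf] <- phi_input[, cf] + meta_shap$phi[, cf]
  # OOF columns: distribute via the base learner's own attributions
  for (b in seq_along(stack$learners)) {
    col <- paste0("oof_", names(stack$learners)[b])
    base_fun <- local({
      models <- stack$fold_models[[b]]
      pp <- stack$learners[[b]]$predict_prob
      function(Z) {
        preds <- vapply(models, function(m) pp(m, Z), numeric(nrow(Z)))
        if (nrow(Z) == 1L) mean(preds) else rowMeans(preds)
      }
    })
    base_shap <- shapley_values(base_fun, X, Xbg)
    w <- abs(base_shap$phi)
    tot <- rowSums(w)
    uniform <- tot <= .Machine$double.eps
    w[uniform, ] <- 1
    w <- w / rowSums(w)
    phi_input <- phi_input + meta_shap$phi[, col] * w
  }
  mean_abs <- colMeans(abs(phi_input))
  summ <- data.frame(feature = names(sort(mean_abs, decreasing = TRUE)),
                     mean_abs_attribution = as.numeric(sort(mean_abs,
                                                            decreasing = TRUE)),
                     stringsAsFactors = FALSE)
  structure(list(summary = summ, phi = phi_input,
                 base_value = meta_shap$base_value,
                 prediction = meta_fun(M), explained = X,
                 n_explained = nrow(X), n_background = nrow(Xbg)),
            class = "dxlr_attribution")
}

#' @export
print.dxlr_attribution <- function(x, ...) {
  cat(sprintf("DXLR feature attribution (%d rows, %d background)\n",
              x$n_explained, x$n_background))
  cat(sprintf("  base value: %.4f\n", x$base_value))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s mean |attribution| = %.4f\n",
                x$summary$feature[i], x$summary$mean_abs_attribution[i]))
  invisible(x)
}

#' Bar plot of mean absolute feature attributions
#'
#' @param x A `dxlr_attribution`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.dxlr_attribution <- function(x, ...) {
  s <- x$summary[nrow(x$summary):1, ]
  graphics::barplot(s$mean_abs_attribution, names.arg = s$feature,
                    horiz = TRUE, las = 1,
                    xlab = "mean |attribution|",
                    main = "DXLR feature attributions", ...)
  invisible(x)
}
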