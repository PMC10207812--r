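#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set to 1:1 by interpolating new minority
#' samples: each synthetic row is drawn on the segment between a random
#' minority row and one of its `k` nearest minority neighbours (Euclidean
#' distance in feature space), at a uniform position. Only ever applied to
#' training folds -- validation and test rows are never resampled.
#'
#' Uses the current RNG stream; callers seed it.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1) of length `nrow(X)`.
#' @param k Number of nearest neighbours (default 5; reduced when the
#'   minority class is smaller).
#' @return List with the augmented `X` and `y` (original rows first,
#'   synthetic rows appended).
#' @export
smote_balance <- function(X, y, k = 5L) {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("SMOTE requires both classes present")
  if (n1 == n0) return(list(X = X, y = y))
  minority <- if (n1 < n0) 1L else 0L
  Xm <- X[y == minority, , drop = FALSE]
  n_min <- nrow(Xm)
  n_new <- abs(n0 - n1)
  if (n_min == 1L) {
    # degenerate: replicate the single minority row
    Xs <- Xm[rep(1L, n_new), , drop = FALSE]
  } else {
    k_eff <- min(k, n_min - 1L)
    D <- as.matrix(stats::dist(Xm))
    diag(D) <- Inf
    nn <- vapply(seq_len(n_min),
                 function(i) order(D[i, ])[seq_len(k_eff)],
                 integer(k_eff))  # k_eff x n_min
    base_i <- sample.int(n_min, n_new, replace = TRUE)
    nb_j <- vapply(base_i, function(i) nn[sample.int(k_eff, 1L), i], 1L)
    gap <- stats::runif(n_new)
    Xs <- Xm[base_i, , drop = FALSE] +
      gap * (Xm[nb_j, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  }
  list(X = rbind(X, Xs), y = c(y, rep(minority, n_new)))
}
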