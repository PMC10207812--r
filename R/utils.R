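# Stratified k-fold assignment: every class is spread as evenly as
# possible over the folds. Returns an integer vector of fold ids in 1..k.
stratified_folds <- function(y, k) {
  y <- as.integer(y)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop(sprintf("class %d has %d rows, fewer than %d folds",
                   cls, length(idx), k))
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Stratified train/test split; returns logical vector TRUE = train.
stratified_split <- function(y, train_frac) {
  y <- as.integer(y)
  train <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_tr <- round(length(idx) * train_frac)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# Derive child seeds from the current RNG stream (kept below 2^31).
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

feature_matrix <- function(data, feature_names) {
  missing_cols <- setdiff(feature_names, colnames(data))
  if (length(missing_cols))
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  X <- data.matrix(data[, feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  X
}
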