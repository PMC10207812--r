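# Independent oracles, deliberately naive implementations.

# Brute-force cosine of two named weight vectors: explicit double loop over
# the union of names for the dot product, full-vector norms.
oracle_cosine <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  dot <- 0
  for (nm in names(a)) {
    if (nm %in% names(b)) dot <- dot + a[[nm]] * b[[nm]]
  }
  na <- sqrt(sum(unlist(a)^2))
  nb <- sqrt(sum(unlist(b)^2))
  if (na == 0 || nb == 0) return(0)
  dot / (na * nb)
}

# All-pairs AUC: every (case, control) pair scores 1 if the case ranks
# higher, 0.5 on ties.
oracle_auc <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# PageRank oracle via igraph (PRPACK), weighted, uniform reset.
oracle_pagerank <- function(net, damping = 0.85) {
  g <- as_igraph(net)
  pr <- igraph::page_rank(g, damping = damping,
                          weights = igraph::E(g)$weight)$vector
  pr[names(net$node_weight)]
}

# Exhaustive PDN edge enumeration: counts every same-admission ordered pair
# (both directions) and every consecutive-admission ordered pair, skipping
# self-loops, via plain nested loops.
oracle_pdn_edges <- function(admissions) {
  admissions <- lapply(admissions, unique)
  acc <- list()
  bump <- function(acc, from, to) {
    if (from == to) return(acc)
    key <- paste(from, to, sep = "->")
    acc[[key]] <- (acc[[key]] %||% 0) + 1
    acc
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (adm in admissions) {
    for (d1 in adm) for (d2 in adm) if (d1 != d2) acc <- bump(acc, d1, d2)
  }
  if (length(admissions) > 1) {
    for (t in seq_len(length(admissions) - 1)) {
      for (d1 in admissions[[t]]) for (d2 in admissions[[t + 1]])
        acc <- bump(acc, d1, d2)
    }
  }
  unlist(acc)
}

# Random weighted disease network on a code alphabet.
random_network <- function(n_nodes, n_edges, kind = "count",
                           codes = sprintf("D%02d", 1:26)) {
  nodes <- sample(codes, n_nodes)
  w <- if (kind == "count") sample(1:5, n_nodes, replace = TRUE)
  else round(stats::runif(n_nodes, 0.05, 1), 3)
  names(w) <- nodes
  ew <- numeric(0)
  if (n_edges > 0 && n_nodes >= 2) {
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ]
    ew <- if (kind == "count") sample(1:4, nrow(pick), replace = TRUE)
    else round(stats::runif(nrow(pick), 0.05, 1), 3)
    names(ew) <- paste(pick$from, pick$to, sep = "->")
  }
  disease_network(w, ew, weight_kind = kind,
                  n_patients = if (kind == "count") 1L else 0L)
}

# Random patient history with n_adm admissions.
random_history <- function(n_adm = 5, codes = sprintf("D%02d", 1:12),
                           pid = "PX") {
  adms <- lapply(seq_len(n_adm), function(i)
    sample(codes, sample(1:4, 1)))
  structure(list(patient_id = pid, sex = "male", age = 70,
                 admissions = adms, indices = seq_len(n_adm)),
            class = "patient_history")
}

# Admission data frame from a list of per-admission code vectors.
history_df <- function(codes_by_admission, pid = "P1", sex = "male",
                       age = 70) {
  data.frame(patient_id = pid, sex = sex, age = age,
             admission_index = seq_along(codes_by_admission),
             diagnoses = vapply(codes_by_admission, paste, "",
                                collapse = ";"),
             stringsAsFactors = FALSE)
}

# Feature table with signal planted in chosen columns: label depends on
# `signal_cols` through a shifted mean, all other features are noise.
synthetic_feature_table <- function(n = 400, signal_cols = "rank_score",
                                    delta = 1.5, case_frac = 1 / 3,
                                    seed = 1) {
  set.seed(seed)
  label <- rbinom(n, 1, case_frac)
  tab <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = round(stats::rnorm(n, 70, 10)),
    sex = rbinom(n, 1, 0.5),
    node_score = stats::runif(n),
    edge_score = stats::runif(n),
    rank_score = stats::runif(n),
    label = label)
  for (col in signal_cols)
    tab[[col]] <- tab[[col]] + delta * label * stats::sd(tab[[col]])
  tab
}
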