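cosine_named <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(0)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(0)
  sum(a[shared] * b[shared]) / den
}

#' Network similarity features of a patient against the DSN
#'
#' `node_score()` is the cosine similarity between the patient's weighted
#' disease vector (PDN node weights) and the DSN's: the dot product runs
#' over shared diseases, the norms over each network's full vector.
#' `edge_score()` is the analogous cosine over directed-edge vectors
#' (edges match only with identical direction). `rank_score()` weights the
#' patient's disease frequencies by the DSN PageRank importance of the
#' shared diseases and divides by the total number of distinct diseases in
#' the PDN. Degenerate inputs (empty vectors, no overlap) score 0: a
#' patient with no DSN overlap is maximally dissimilar.
#'
#' @param pdn The patient's `disease_network`.
#' @param dsn The frozen disease-specific `disease_network`.
#' @param pr A `pagerank_map` computed on the DSN.
#' @return A single numeric score (`node_score`/`edge_score` in [0, 1] for
#'   nonnegative weights; `rank_score >= 0`).
#' @export
node_score <- function(pdn, dsn) {
  cosine_named(pdn$node_weight, dsn$node_weight)
}

#' @rdname node_score
#' @export
edge_score <- function(pdn, dsn) {
  cosine_named(pdn$edge_weight, dsn$edge_weight)
}

#' @rdname node_score
#' @export
rank_score <- function(pdn, pr) {
  v <- pdn$node_weight
  if (!length(v)) return(0)
  shared <- intersect(names(v), names(pr))
  if (!length(shared)) return(0)
  sum(v[shared] * unclass(pr)[shared]) / length(v)
}

#' Assemble the model-ready feature table
#'
#' One row per requested patient with the five model inputs -- age, sex
#' (male = 1), node score, edge score, rank score -- and the binary label
#' (case = 1). Case histories are censored at the first HF admission before
#' the PDN is built, so features carry only pre-outcome information.
#'
#' @param histories List of `patient_history` objects (all patients).
#' @param assignments Output of [assign_cohorts()].
#' @param dsn Frozen disease-specific network (from the network partition).
#' @param pr `pagerank_map` on `dsn`.
#' @param patient_ids Patients to score (typically the modeling partition);
#'   default: all included patients.
#' @param censor Censor case histories before feature extraction (default
#'   TRUE).
#' @return Data frame `patient_id, age, sex, node_score, edge_score,
#'   rank_score, label`.
#' @export
build_feature_table <- function(histories, assignments, dsn, pr,
                                patient_ids = NULL, censor = TRUE) {
  by_id <- stats::setNames(histories,
                           vapply(histories, `[[`, "", "patient_id"))
  included <- assignments[assignments$group %in% c("case", "control"), ,
                          drop = FALSE]
  if (is.null(patient_ids)) patient_ids <- included$patient_id
  missing_ids <- setdiff(patient_ids, included$patient_id)
  if (length(missing_ids))
    stop(sprintf("patient(s) not in the included cohorts: %s",
                 paste(utils::head(missing_ids, 5L), collapse = ", ")))
  rows <- vector("list", length(patient_ids))
  for (i in seq_along(patient_ids)) {
    pid <- patient_ids[i]
    a <- included[included$patient_id == pid, , drop = FALSE]
    h <- by_id[[pid]]
    if (is.null(h))
      stop(sprintf("no history available for patient %s", pid))
    if (a$group == "case" && censor) h <- censor_case_history(h, a)
    if (!length(h$admissions))
      stop(sprintf("patient %s has no admissions to build a PDN from", pid))
    pdn <- build_pdn(h)
    rows[[i]] <- data.frame(
      patient_id = pid,
      age = h$age,
      sex = as.integer(h$sex == "male"),
      node_score = node_score(pdn, dsn),
      edge_score = edge_score(pdn, dsn),
      rank_score = rank_score(pdn, pr),
      label = as.integer(a$group == "case"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (anyNA(out)) stop("feature table contains missing values")
  rownames(out) <- NULL
  out
}

#' Run the full network-feature extraction pipeline
#'
#' From raw admission rows to the model-ready feature table: cleans the
#' records, assembles histories, applies the cohort rules, splits included
#' patients into a network-construction partition (default 65%) and a
#' modeling partition, builds the case and control baseline networks from
#' the network partition (case histories censored), derives the
#' disease-specific network and its PageRank, and scores the modeling
#' partition against the frozen DSN.
#'
#' @param records Raw admission rows (schema of [generate_population()]).
#' @param network_fraction Share of included patients used for network
#'   construction (default 0.65).
#' @param split_seed Seed for the stratified network/modeling split.
#' @param censor Censor case histories before network and feature
#'   construction (default TRUE).
#' @param dsn_method,epsilon Passed to [build_dsn()].
#' @param damping Passed to [pagerank()].
#' @return List of class `hfnet_pipeline`: `features` (modeling-partition
#'   feature table), `dsn`, `pagerank`, `bdn_case`, `bdn_control`,
#'   `assignments`, `split`, `cleaning`.
#' @export
extract_network_features <- function(records, network_fraction = 0.65,
                                     split_seed = 1L, censor = TRUE,
                                     dsn_method = "difference_clamped",
                                     epsilon = 1e-9, damping = 0.85) {
  cleaned <- clean_records(records)
  built <- build_histories(cleaned$records)
  histories <- built$histories
  assignments <- assign_cohorts(histories)
  split <- split_network_vs_modeling(assignments, fraction = network_fraction,
                                     seed = split_seed)
  by_id <- stats::setNames(histories,
                           vapply(histories, `[[`, "", "patient_id"))
  pdn_for <- function(pid) {
    a <- assignments[assignments$patient_id == pid, , drop = FALSE]
    h <- by_id[[pid]]
    if (a$group == "case" && censor) h <- censor_case_history(h, a)
    build_pdn(h)
  }
  grp <- stats::setNames(assignments$group, assignments$patient_id)
  net_case <- split$network_ids[grp[split$network_ids] == "case"]
  net_ctrl <- split$network_ids[grp[split$network_ids] == "control"]
  if (!length(net_case) || !length(net_ctrl))
    stop("network partition must contain both cases and controls")
  bdn_case <- to_relative_frequency(merge_bdn(lapply(net_case, pdn_for)))
  bdn_ctrl <- to_relative_frequency(merge_bdn(lapply(net_ctrl, pdn_for)))
  dsn <- build_dsn(bdn_case, bdn_ctrl, method = dsn_method, epsilon = epsilon)
  pr <- pagerank(dsn, damping = damping)
  features <- build_feature_table(histories, assignments, dsn, pr,
                                  patient_ids = split$modeling_ids,
                                  censor = censor)
  structure(list(features = features, dsn = dsn, pagerank = pr,
                 bdn_case = bdn_case, bdn_control = bdn_ctrl,
                 assignments = assignments, split = split,
                 cleaning = cleaned$dropped,
                 dropped_inconsistent = built$dropped_inconsistent),
            class = "hfnet_pipeline")
}

#' @export
print.hfnet_pipeline <- function(x, ...) {
  tab <- table(x$assignments$group)
  cat("Network feature pipeline\n")
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  network partition: %d patients; modeling partition: %d\n",
              length(x$split$network_ids), length(x$split$modeling_ids)))
  cat(sprintf("  DSN: %d nodes, %d edges\n",
              length(x$dsn$node_weight), length(x$dsn$edge_weight)))
  cat(sprintf("  feature table: %d rows (%d cases)\n",
              nrow(x$features), sum(x$features$label)))
  invisible(x)
}

#' Write the feature table CSV
#'
#' @param features Output of [build_feature_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
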