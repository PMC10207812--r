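edge_key <- function(from, to) paste(from, to, sep = "->")

edge_endpoints <- function(keys) {
  if (!length(keys))
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "->", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1L),
             to = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Construct a disease network object
#'
#' A weighted directed graph over ICD-10 category codes. The same container
#' serves as a personal disease network (PDN, per-patient admission counts),
#' a baseline disease network (BDN, cohort-wide sums or per-patient relative
#' frequencies) and a disease-specific network (DSN, case-vs-control
#' specificity weights).
#'
#' @param node_weight Named nonnegative numeric vector (code -> weight).
#' @param edge_weight Named numeric vector keyed `"FROM->TO"`; endpoints
#'   must appear in `node_weight` and self-loops are forbidden.
#' @param weight_kind One of `"count"`, `"relative_frequency"`,
#'   `"specificity"`.
#' @param n_patients Number of patients aggregated (1 for a PDN).
#' @param allow_negative Permit negative weights (used only by the signed
#'   DSN strategy).
#' @return An object of class `disease_network`.
#' @export
disease_network <- function(node_weight, edge_weight = numeric(0),
                            weight_kind = c("count", "relative_frequency",
                                            "specificity"),
                            n_patients = 1L, allow_negative = FALSE) {
  weight_kind <- match.arg(weight_kind)
  node_weight <- unlist(node_weight)
  if (length(node_weight) && is.null(names(node_weight)))
    stop("node_weight must be named by disease code")
  edge_weight <- unlist(edge_weight)
  if (is.null(edge_weight)) edge_weight <- numeric(0)
  if (length(edge_weight)) {
    if (is.null(names(edge_weight))) stop("edge_weight must be keyed FROM->TO")
    ep <- edge_endpoints(names(edge_weight))
    if (any(ep$from == ep$to)) stop("self-loop edges are not allowed")
    missing_ep <- setdiff(unique(c(ep$from, ep$to)), names(node_weight))
    if (length(missing_ep))
      stop(sprintf("edge endpoint(s) absent from node set: %s",
                   paste(missing_ep, collapse = ", ")))
  }
  if (!allow_negative && (any(node_weight < 0) || any(edge_weight < 0)))
    stop("network weights must be nonnegative")
  if (weight_kind == "count" &&
      (any(node_weight != round(node_weight)) ||
       any(edge_weight != round(edge_weight))))
    stop("count-weighted networks must have integral weights")
  structure(list(node_weight = node_weight, edge_weight = edge_weight,
                 weight_kind = weight_kind, n_patients = as.integer(n_patients)),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("Disease network (%s): %d nodes, %d edges, %d patient(s)\n",
              x$weight_kind, length(x$node_weight), length(x$edge_weight),
              x$n_patients))
  invisible(x)
}

sum_named <- function(...) {
  v <- c(...)
  if (!length(v)) return(numeric(0))
  c(tapply(v, names(v), sum)[unique(names(v))])
}

#' Build a personal disease network from one patient's history
#'
#' Node weight of a disease is the number of admissions in which it appears.
#' Edge weights count co-occurrences in the same or consecutive admissions:
#' within an admission every ordered pair of distinct codes contributes 1 to
#' both directions; across consecutive admissions each (code in t, code in
#' t+1) pair contributes 1 to the forward edge. Self-loops are excluded (a
#' recurring disease is captured by its node weight).
#'
#' @param history A `patient_history` (admission code sets, temporally
#'   ordered).
#' @return A `disease_network` with `weight_kind = "count"`.
#' @export
build_pdn <- function(history) {
  adms <- history$admissions
  if (!length(adms)) stop("cannot build a PDN from an empty history")
  adms <- lapply(adms, unique)
  nodes <- sum_named(unlist(lapply(adms, function(a) {
    w <- rep(1, length(a)); names(w) <- a; w
  })))
  keys <- character(0)
  for (a in adms) {
    if (length(a) >= 2L) {
      pairs <- expand.grid(from = a, to = a, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
      keys <- c(keys, edge_key(pairs$from, pairs$to))
    }
  }
  if (length(adms) >= 2L) {
    for (t in seq_len(length(adms) - 1L)) {
      pairs <- expand.grid(from = adms[[t]], to = adms[[t + 1L]],
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
      keys <- c(keys, edge_key(pairs$from, pairs$to))
    }
  }
  edges <- if (length(keys)) {
    w <- rep(1, length(keys)); names(w) <- keys; sum_named(w)
  } else numeric(0)
  disease_network(nodes, edges, weight_kind = "count", n_patients = 1L)
}

#' Merge personal disease networks into a baseline disease network
#'
#' Node and edge weights are elementwise sums over the constituent PDNs;
#' `n_patients` is the number of networks merged.
#'
#' @param pdns Non-empty list of count-weighted `disease_network`s.
#' @return A count-weighted `disease_network`.
#' @export
merge_bdn <- function(pdns) {
  if (!length(pdns)) stop("cannot merge an empty list of networks")
  kinds <- vapply(pdns, function(p) p$weight_kind, "")
  if (!all(kinds == "count"))
    stop("merge_bdn() requires count-weighted networks")
  nodes <- sum_named(unlist(lapply(pdns, `[[`, "node_weight")))
  edges <- sum_named(unlist(lapply(pdns, `[[`, "edge_weight")))
  if (is.null(edges)) edges <- numeric(0)
  disease_network(nodes, edges, weight_kind = "count",
                  n_patients = sum(vapply(pdns, function(p) p$n_patients, 1L)))
}

#' Convert a count-weighted baseline network to relative frequencies
#'
#' Divides every node and edge weight by the number of patients aggregated,
#' removing the dependence of cohort network weights on cohort size.
#'
#' @param bdn A count-weighted `disease_network` with `n_patients >= 1`.
#' @return A `disease_network` with `weight_kind = "relative_frequency"`.
#' @export
to_relative_frequency <- function(bdn) {
  stopifnot(inherits(bdn, "disease_network"))
  if (bdn$weight_kind != "count")
    stop("to_relative_frequency() requires a count-weighted network")
  if (bdn$n_patients < 1L) stop("network aggregates zero patients")
  disease_network(bdn$node_weight / bdn$n_patients,
                  bdn$edge_weight / bdn$n_patients,
                  weight_kind = "relative_frequency",
                  n_patients = bdn$n_patients)
}

#' Build the disease-specific network
#'
#' Contrasts the case and control baseline networks (both in relative
#' frequencies). The default `"difference_clamped"` strategy sets each
#' node/edge weight to `max(0, case - control)` -- comorbidities more
#' prevalent along the IHD-to-HF trajectory gain weight, the opposite
#' conditions are dropped. Zero-weight entries are removed; nodes that
#' anchor a surviving edge but lost all weight are retained at a small
#' floor `epsilon` so every edge keeps its endpoints.
#' `"difference_signed"` keeps the signed difference instead.
#'
#' @param bdn_case_rf,bdn_control_rf Relative-frequency
#'   `disease_network`s for the case and control cohorts.
#' @param method Specificity strategy (see above).
#' @param epsilon Weight floor for retained zero-weight edge endpoints.
#' @return A `disease_network` with `weight_kind = "specificity"`.
#' @export
build_dsn <- function(bdn_case_rf, bdn_control_rf,
                      method = c("difference_clamped", "difference_signed"),
                      epsilon = 1e-9) {
  method <- match.arg(method)
  for (x in list(bdn_case_rf, bdn_control_rf))
    if (!inherits(x, "disease_network") || x$weight_kind != "relative_frequency")
      stop("build_dsn() requires relative-frequency networks")
  diff_named <- function(a, b) {
    nm <- union(names(a), names(b))
    av <- ifelse(nm %in% names(a), a[nm], 0)
    bv <- ifelse(nm %in% names(b), b[nm], 0)
    d <- av - bv
    names(d) <- nm
    d
  }
  nd <- diff_named(bdn_case_rf$node_weight, bdn_control_rf$node_weight)
  ed <- diff_named(bdn_case_rf$edge_weight, bdn_control_rf$edge_weight)
  if (method == "difference_clamped") {
    nd <- nd[nd > 0]
    ed <- ed[ed > 0]
  } else {
    nd <- nd[nd != 0]
    ed <- ed[ed != 0]
  }
  ep <- edge_endpoints(names(ed))
  orphan <- setdiff(unique(c(ep$from, ep$to)), names(nd))
  if (length(orphan)) {
    floor_w <- rep(epsilon, length(orphan))
    names(floor_w) <- orphan
    nd <- c(nd, floor_w)
  }
  disease_network(nd, ed, weight_kind = "specificity", n_patients = 0L,
                  allow_negative = (method == "difference_signed"))
}

#' Weighted PageRank over the disease-specific network
#'
#' Power iteration with uniform teleportation: from node `u` the walk
#' follows edge `u -> v` with probability proportional to its weight;
#' dangling nodes redistribute uniformly. Iterates until the L1 change
#' falls below `tol` (at most `max_iter` sweeps).
#'
#' @param dsn A non-empty `disease_network`.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Iteration cap; default 1000.
#' @return Named numeric vector of scores summing to 1 (class
#'   `pagerank_map`, with the damping factor as attribute).
#' @export
pagerank <- function(dsn, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(dsn, "disease_network"))
  nodes <- names(dsn$node_weight)
  n <- length(nodes)
  if (n == 0L) stop("cannot compute PageRank on an empty network")
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (length(dsn$edge_weight)) {
    ep <- edge_endpoints(names(dsn$edge_weight))
    if (any(dsn$edge_weight < 0))
      stop("PageRank requires nonnegative edge weights")
    W[cbind(match(ep$from, nodes), match(ep$to, nodes))] <- dsn$edge_weight
  }
  out_w <- rowSums(W)
  dangling <- out_w == 0
  P <- W
  P[!dangling, ] <- P[!dangling, , drop = FALSE] / out_w[!dangling]
  p <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    p_new <- damping * (crossprod(P, p)[, 1L] + sum(p[dangling]) / n) +
      (1 - damping) / n
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  p <- p / sum(p)
  names(p) <- nodes
  structure(p, class = "pagerank_map", damping = damping, iterations = iter)
}

#' @export
print.pagerank_map <- function(x, ...) {
  cat(sprintf("PageRank over %d nodes (damping %.2f, %d iterations)\n",
              length(x), attr(x, "damping"), attr(x, "iterations")))
  v <- sort(unclass(x), decreasing = TRUE)
  print(utils::head(v, 10L))
  invisible(x)
}

#' Split patients into network-construction and modeling partitions
#'
#' Patient-level split, stratified by cohort group, of all non-excluded
#' patients: a `fraction` share (rounded down per group) builds the
#' networks, the remainder trains and tests the models. The
#' disease-specific network must be frozen on the network partition before
#' any model sees the modeling partition.
#'
#' @param assignments Output of [assign_cohorts()].
#' @param fraction Share of each group allotted to network construction
#'   (default 0.65).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with character vectors `network_ids` and `modeling_ids`.
#' @export
split_network_vs_modeling <- function(assignments, fraction = 0.65, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  network_ids <- character(0)
  modeling_ids <- character(0)
  for (g in c("case", "control")) {
    ids <- assignments$patient_id[assignments$group == g]
    n_net <- floor(length(ids) * fraction)
    net <- if (n_net > 0) sample(ids, n_net) else character(0)
    network_ids <- c(network_ids, net)
    modeling_ids <- c(modeling_ids, setdiff(ids, net))
  }
  list(network_ids = network_ids, modeling_ids = modeling_ids)
}

#' Serialize a disease network
#'
#' `write_network_csv()` writes an edge list (`from,to,weight`) and a node
#' table (`code,weight`, plus `pagerank` when supplied).
#' `write_network_graphml()` exports the graph with weights as attributes
#' via igraph.
#'
#' @param net A `disease_network`.
#' @param edge_path,node_path,path Output file paths.
#' @param pr Optional `pagerank_map` to include in the node table.
#' @return The written path(s), invisibly.
#' @export
write_network_csv <- function(net, edge_path, node_path, pr = NULL) {
  ep <- edge_endpoints(names(net$edge_weight))
  ep$weight <- as.numeric(net$edge_weight)
  utils::write.csv(ep, edge_path, row.names = FALSE)
  nodes <- data.frame(code = names(net$node_weight),
                      weight = as.numeric(net$node_weight),
                      stringsAsFactors = FALSE)
  if (!is.null(pr)) nodes$pagerank <- as.numeric(pr[nodes$code])
  utils::write.csv(nodes, node_path, row.names = FALSE)
  invisible(c(edge_path, node_path))
}

#' @rdname write_network_csv
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a disease network to an igraph object
#'
#' @param net A `disease_network`.
#' @return An igraph directed graph with `weight` attributes on vertices
#'   and edges.
#' @export
as_igraph <- function(net) {
  ep <- edge_endpoints(names(net$edge_weight))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ep$from, to = ep$to,
               weight = as.numeric(net$edge_weight),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = names(net$node_weight),
                          weight = as.numeric(net$node_weight),
                          stringsAsFactors = FALSE))
  g
}
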