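test_that("PDN counting follows the same/consecutive-admission rules", {
  pdn <- build_pdn(mk_history(list(c("A", "B"), "C")))
  expect_equal(sort(names(pdn$node_weight)), c("A", "B", "C"))
  expect_equal(unname(pdn$node_weight[c("A", "B", "C")]), c(1, 1, 1))
  expect_equal(pdn$edge_weight[["A->B"]], 1)
  expect_equal(pdn$edge_weight[["B->A"]], 1)
  expect_equal(pdn$edge_weight[["A->C"]], 1)
  expect_equal(pdn$edge_weight[["B->C"]], 1)
  expect_length(pdn$edge_weight, 4L)

  single <- build_pdn(mk_history(list("A")))
  expect_equal(unname(single$node_weight), 1)
  expect_length(single$edge_weight, 0L)

  recurring <- build_pdn(mk_history(list("A", "A")))
  expect_equal(unname(recurring$node_weight[["A"]]), 2)
  expect_length(recurring$edge_weight, 0L)  # self-loops excluded

  expect_error(build_pdn(mk_history(list())), "empty")
})

test_that("PDN edges agree with the brute-force pair-enumeration oracle", {
  set.seed(42)
  for (i in 1:25) {
    h <- random_history(n_adm = 5)
    pdn <- build_pdn(h)
    expected <- oracle_pdn_edges(h$admissions)
    if (is.null(expected)) {
      expect_length(pdn$edge_weight, 0L)
    } else {
      expect_mapequal(as.list(pdn$edge_weight), as.list(expected))
    }
    # node weights equal admission membership counts
    for (code in names(pdn$node_weight)) {
      expect_equal(pdn$node_weight[[code]],
                   sum(vapply(h$admissions, function(a) code %in% a,
                              logical(1))))
    }
  }
})

test_that("BDN merging sums weights and conserves totals", {
  p1 <- disease_network(c(A = 1), weight_kind = "count")
  p2 <- disease_network(c(A = 2, B = 1), c(`A->B` = 1, `B->A` = 1),
                        weight_kind = "count")
  merged1 <- merge_bdn(list(p1))
  expect_equal(merged1$node_weight, p1$node_weight)
  expect_equal(merged1$n_patients, 1L)

  bdn <- merge_bdn(list(p1, p2))
  expect_equal(bdn$node_weight[["A"]], 3)
  expect_equal(bdn$node_weight[["B"]], 1)
  expect_equal(bdn$n_patients, 2L)

  set.seed(7)
  pdns <- lapply(1:20, function(i) build_pdn(random_history()))
  big <- merge_bdn(pdns)
  expect_equal(sum(big$node_weight),
               sum(vapply(pdns, function(p) sum(p$node_weight), 0)))
  expect_equal(sum(big$edge_weight),
               sum(vapply(pdns, function(p) sum(p$edge_weight), 0)))
  expect_error(merge_bdn(list()), "empty")
})

test_that("relative-frequency normalisation divides by patient count", {
  bdn <- disease_network(c(A = 10), c(), weight_kind = "count",
                         n_patients = 20L)
  rf <- to_relative_frequency(bdn)
  expect_equal(rf$node_weight[["A"]], 0.5)
  expect_equal(rf$weight_kind, "relative_frequency")

  one <- to_relative_frequency(
    disease_network(c(A = 3), weight_kind = "count", n_patients = 1L))
  expect_equal(one$node_weight[["A"]], 3)

  # a disease on every admission of every patient: relative node weight
  # equals the mean number of admissions per patient
  set.seed(1)
  n_adm <- sample(2:6, 10, replace = TRUE)
  pdns <- lapply(n_adm, function(k)
    build_pdn(mk_history(lapply(seq_len(k), function(i) c("Z", "Q")))))
  rf2 <- to_relative_frequency(merge_bdn(pdns))
  expect_equal(rf2$node_weight[["Z"]], mean(n_adm))
  expect_error(to_relative_frequency(rf), "count")
})

test_that("DSN weights are clamped case-minus-control differences", {
  case_rf <- disease_network(c(A = 0.8, B = 0.2, C = 0.4),
                             c(`A->C` = 0.5, `C->A` = 0.1),
                             weight_kind = "relative_frequency")
  ctrl_rf <- disease_network(c(A = 0.3, B = 0.6, C = 0.4),
                             c(`A->C` = 0.2, `C->A` = 0.3),
                             weight_kind = "relative_frequency")
  dsn <- build_dsn(case_rf, ctrl_rf)
  expect_equal(dsn$node_weight[["A"]], 0.5)
  expect_false("B" %in% names(dsn$node_weight))  # clamped to zero, removed
  expect_equal(dsn$edge_weight[["A->C"]], 0.3)
  expect_false("C->A" %in% names(dsn$edge_weight))
  # C's node weight vanished but it anchors A->C: kept at the epsilon floor
  expect_true("C" %in% names(dsn$node_weight))
  expect_equal(dsn$node_weight[["C"]], 1e-9)

  empty <- build_dsn(case_rf, case_rf)
  expect_length(empty$node_weight, 0L)
  expect_length(empty$edge_weight, 0L)

  signed <- build_dsn(case_rf, ctrl_rf, method = "difference_signed")
  expect_equal(signed$node_weight[["B"]], -0.4)

  expect_error(build_dsn(case_rf, to_relative_frequency(
    disease_network(c(A = 1), weight_kind = "count"))$node_weight),
    "relative-frequency")
})

test_that("DSN weights are bounded by the case relative frequencies", {
  set.seed(11)
  for (i in 1:10) {
    ca <- random_network(8, 16, kind = "relative_frequency")
    co <- random_network(8, 16, kind = "relative_frequency")
    dsn <- build_dsn(ca, co)
    expect_true(all(dsn$node_weight >= 0))
    expect_true(all(dsn$edge_weight >= 0))
    shared <- setdiff(names(dsn$node_weight), character(0))
    for (nm in shared)
      expect_lte(dsn$node_weight[[nm]],
                 if (nm %in% names(ca$node_weight))
                   ca$node_weight[[nm]] else 1e-9)
  }
})

test_that("PageRank matches closed forms on elementary graphs", {
  two <- disease_network(c(A = 1, B = 1), c(`A->B` = 1, `B->A` = 1),
                         weight_kind = "count")
  pr <- pagerank(two)
  expect_equal(unname(unclass(pr)[c("A", "B")]), c(0.5, 0.5),
               tolerance = 1e-9)

  lone <- pagerank(disease_network(c(A = 1), weight_kind = "count"))
  expect_equal(as.numeric(lone), 1.0)

  cycle <- disease_network(c(A = 1, B = 1, C = 1),
                           c(`A->B` = 1, `B->C` = 1, `C->A` = 1),
                           weight_kind = "count")
  pr3 <- pagerank(cycle)
  expect_equal(as.numeric(pr3), rep(1 / 3, 3), tolerance = 1e-9)

  expect_error(pagerank(disease_network(numeric(0))), "empty")
})

test_that("PageRank sums to one, is a fixed point, and matches igraph", {
  set.seed(99)
  for (i in 1:50) {
    net <- random_network(sample(2:10, 1), sample(1:20, 1),
                          kind = "relative_frequency")
    pr <- pagerank(net)
    expect_equal(sum(pr), 1, tolerance = 1e-9)

    # fixed point of the damped transition operator
    nodes <- names(net$node_weight)
    n <- length(nodes)
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (length(net$edge_weight)) {
      ep <- do.call(rbind, strsplit(names(net$edge_weight), "->", fixed = TRUE))
      W[cbind(match(ep[, 1], nodes), match(ep[, 2], nodes))] <- net$edge_weight
    }
    out_w <- rowSums(W)
    P <- W
    P[out_w > 0, ] <- P[out_w > 0, , drop = FALSE] / out_w[out_w > 0]
    p <- unclass(pr)[nodes]
    p_next <- 0.85 * (as.numeric(crossprod(P, p)) + sum(p[out_w == 0]) / n) +
      0.15 / n
    expect_lt(max(abs(p_next - p)), 1e-8)

    # independent oracle (igraph/PRPACK)
    expect_equal(unname(unclass(pr)[nodes]),
                 unname(oracle_pagerank(net)[nodes]), tolerance = 1e-7)
  }
})

test_that("network/modeling split is stratified, disjoint and exhaustive", {
  asg <- data.frame(
    patient_id = sprintf("P%03d", 1:310),
    group = c(rep("case", 100), rep("control", 200), rep("excluded", 10)),
    stringsAsFactors = FALSE)
  sp <- split_network_vs_modeling(asg, fraction = 0.65, seed = 4)
  grp <- setNames(asg$group, asg$patient_id)
  expect_equal(sum(grp[sp$network_ids] == "case"), 65L)
  expect_equal(sum(grp[sp$network_ids] == "control"), 130L)
  expect_length(intersect(sp$network_ids, sp$modeling_ids), 0L)
  expect_setequal(c(sp$network_ids, sp$modeling_ids),
                  asg$patient_id[asg$group != "excluded"])
  sp2 <- split_network_vs_modeling(asg, fraction = 0.65, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_network_vs_modeling(asg, fraction = 1.2), "fraction")
})

test_that("network serialization round-trips through CSV and GraphML", {
  set.seed(3)
  net <- random_network(6, 10, kind = "relative_frequency")
  pr <- pagerank(net)
  e <- tempfile(fileext = ".csv"); v <- tempfile(fileext = ".csv")
  g <- tempfile(fileext = ".graphml")
  write_network_csv(net, e, v, pr = pr)
  edges <- utils::read.csv(e, stringsAsFactors = FALSE)
  nodes <- utils::read.csv(v, stringsAsFactors = FALSE)
  expect_setequal(paste(edges$from, edges$to, sep = "->"),
                  names(net$edge_weight))
  expect_equal(setNames(nodes$weight, nodes$code)[names(net$node_weight)],
               net$node_weight)
  expect_equal(sum(nodes$pagerank), 1, tolerance = 1e-9)
  write_network_graphml(net, g)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_setequal(igraph::V(gg)$name, names(net$node_weight))
  expect_equal(igraph::ecount(gg), length(net$edge_weight))
  unlink(c(e, v, g))
})
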