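test_that("threshold metrics reproduce the confusion-table formulas", {
  m <- metrics_from_confusion(tp = 3, fp = 1, tn = 5, fn = 1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)

  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(.9, .8, .7, .4, .6, .3, .2, .1, .1, .2)  # tp3 fn1 fp1 tn5
  cm <- compute_metrics(y, p)
  expect_equal(cm[c("tp", "fp", "tn", "fn")],
               list(tp = 3L, fp = 1L, tn = 5L, fn = 1L))
  expect_equal(cm[c("precision", "recall", "accuracy", "f1")],
               list(precision = 0.75, recall = 0.75, accuracy = 0.8,
                    f1 = 0.75))

  perfect <- compute_metrics(c(0, 1, 0, 1), c(.1, .9, .2, .8))
  expect_true(all(unlist(perfect[c("precision", "recall", "accuracy",
                                   "f1", "auc")]) == 1))

  reversed <- compute_metrics(c(0, 1, 0, 1), c(.9, .1, .8, .2))
  expect_equal(reversed$auc, 0)

  expect_warning(z <- compute_metrics(c(0, 1), c(.1, .2), threshold = 0.9),
                 "precision undefined")
  expect_equal(z$precision, 0)
})

test_that("F1 is the harmonic mean of precision and recall", {
  set.seed(20)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- runif(50)
    m <- suppressWarnings(compute_metrics(y, p))
    if (m$precision > 0 && m$recall > 0)
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
    expect_equal(m$accuracy, 1 - (m$fp + m$fn) / 50)
  }
})

test_that("rank-based AUC equals the all-pairs oracle, ties at one half", {
  set.seed(14)
  for (i in 1:5) {
    y <- rbinom(500, 1, 0.35)
    p <- round(runif(500), 2)  # rounding forces ties
    expect_equal(auc_score(y, p), oracle_auc(y, p), tolerance = 1e-12)
  }
  expect_error(auc_score(rep(1, 5), runif(5)), "single class")
  single <- suppressWarnings(compute_metrics(rep(1, 5), runif(5)))
  expect_true(is.na(single$auc))
  expect_false(is.na(single$recall))
})

test_that("repeated-split reports are deterministic with zero-SD stubs", {
  tab <- synthetic_feature_table(120, seed = 3)
  expect_error(repeated_split_evaluation(tab, models = "lr", n_repeats = 1),
               "n_repeats")
  rep1 <- repeated_split_evaluation(
    tab, models = list(const = learner_constant(0.7)), n_repeats = 2,
    smote = FALSE, seed = 5)
  # constant classifier: every metric identical across repeats
  sds <- rep1$summary$sd[rep1$summary$metric != "auc"]
  expect_true(all(sds == 0))
  rep2 <- repeated_split_evaluation(tab, models = "dt", n_repeats = 3,
                                    seed = 7)
  rep3 <- repeated_split_evaluation(tab, models = "dt", n_repeats = 3,
                                    seed = 7)
  expect_identical(rep2$summary, rep3$summary)
  expect_equal(nrow(rep2$per_repeat), 3L)
})

test_that("planted signal is found and evaluation never touches test rows", {
  tab <- synthetic_feature_table(400, signal_cols = "rank_score",
                                 delta = 2, seed = 9)
  rep <- repeated_split_evaluation(tab, models = c("dt", "lr"),
                                   n_repeats = 3, seed = 1)
  expect_gt(report_metric(rep, "dt", "auc"), 0.8)
  expect_gt(report_metric(rep, "lr", "auc"), 0.8)
  tt <- compare_models(rep, "dt", "lr")
  expect_s3_class(tt, "htest")
})

test_that("ablation reports four variants and spares noise features", {
  # signal only in node_score: edge_score is pure noise
  tab <- synthetic_feature_table(400, signal_cols = "node_score",
                                 delta = 2, seed = 12)
  tab$age <- round(rnorm(400, 70, 10))  # demographics carry no signal
  ab <- ablation_network_features(tab, models = "dt", n_repeats = 4,
                                  seed = 3)
  expect_setequal(unique(ab$variant), c("full", "-Node", "-Edge", "-Rank"))
  auc_of <- function(v) ab$mean[ab$variant == v & ab$metric == "auc"]
  # dropping a pure-noise feature barely moves the AUC
  expect_lt(abs(auc_of("full") - auc_of("-Edge")), 0.02)
  # dropping the only signal feature collapses discrimination
  expect_lt(auc_of("-Node"), 0.62)
  expect_gt(auc_of("full"), 0.85)
})

test_that("subgroup analysis stratifies only the test-set evaluation", {
  tab <- synthetic_feature_table(500, signal_cols = "rank_score",
                                 delta = 2, seed = 15)
  tab$age <- round(runif(500, 20, 95))  # age-independent signal
  sg <- subgroup_analysis(tab, model = "dt", n_repeats = 4, seed = 2)
  s <- sg$summary
  expect_true(all(c("pooled", "male", "female") %in% s$subgroup))
  # both sexes present -> two sex rows
  expect_equal(sum(s$subgroup %in% c("male", "female") &
                     s$metric == "auc"), 2L)
  # age-independent signal: AUC bands overlap across age bins
  age_rows <- s[s$metric == "auc" &
                  s$subgroup %in% c("18-44", "45-59", "60-69", "70-79",
                                    "80+"), ]
  expect_gt(nrow(age_rows), 1L)
  # age-independent signal: the mean ± 2 SD bands share a common region
  expect_lte(max(age_rows$mean - 2 * age_rows$sd),
             min(age_rows$mean + 2 * age_rows$sd))
  expect_true(all(c("sex", "age") %in% names(sg$tests$auc)))
})

test_that("exact Shapley attributions are additive and null for constants", {
  set.seed(30)
  X <- matrix(runif(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, "c"] <- 0.5  # constant feature
  bg <- X[1:15, ]
  f <- function(Z) Z[, "a"] * 2 + Z[, "b"] * Z[, "a"]
  sh <- shapley_values(f, X, bg)
  expect_equal(rowSums(sh$phi), f(X) - mean(f(bg)), tolerance = 1e-10)
  expect_equal(unname(sh$phi[, "c"]), rep(0, 40), tolerance = 1e-12)

  # linear model, independent background: attribution proportional to
  # the centred feature
  g <- function(Z) 3 * Z[, "a"]
  sh2 <- shapley_values(g, X, bg)
  expect_equal(unname(sh2$phi[, "a"]),
               unname(3 * (X[, "a"] - mean(bg[, "a"]))), tolerance = 1e-10)
  expect_equal(max(abs(sh2$phi[, c("b", "c")])), 0, tolerance = 1e-12)
})

test_that("DXLR attributions are additive and rank the planted feature first", {
  tab <- synthetic_feature_table(220, signal_cols = "rank_score",
                                 delta = 2.5, seed = 18)
  fit <- dxlr(label ~ age + sex + node_score + edge_score + rank_score,
              tab, seed = 21)
  att <- attribution_summary(fit, tab, n_background = 25, max_explain = 60,
                             seed = 2)
  expect_equal(att$summary$feature[1], "rank_score")
  expect_equal(nrow(att$phi), 60L)
  # signed per-row attributions sum to prediction minus base value
  expect_equal(unname(rowSums(att$phi)),
               att$prediction - att$base_value, tolerance = 1e-6)
  # a constant column earns no attribution
  tab2 <- tab
  tab2$sex <- 1L
  fit2 <- dxlr(label ~ age + sex + node_score + edge_score + rank_score,
               tab2, seed = 21)
  att2 <- attribution_summary(fit2, tab2, n_background = 20,
                              max_explain = 40, seed = 3)
  expect_equal(max(abs(att2$phi[, "sex"])), 0, tolerance = 1e-12)
})
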