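# Threshold selection, target sets and enrichment evaluation.

test_that("multiple-binding scores read the knockdown column", {
  m <- rbind(G1 = c(3, 0), G2 = c(0, 5), G3 = c(2.5, 1))
  colnames(m) <- c("c1", "c2")
  mb <- multiple_binding_scores(m, "c1")
  expect_equal(mb$score[mb$gene_id == "G1"], 3)
  expect_true(mb$valid[mb$gene_id == "G1"])
  expect_false(mb$valid[mb$gene_id == "G2"])   # no peak in knockdown cell
  expect_equal(mb$score[mb$gene_id == "G3"], 2.5)  # magnitude-mode reals
  expect_true(all(mb$sign == "n/a"))
  expect_error(multiple_binding_scores(m, "c9"), "available: c1, c2")
})

test_that("evaluation universes follow the per-method validity rules", {
  scores <- rbind(
    toy_scores(c(g1 = .9, g2 = .8, g3 = .7, g4 = .6), "PC",
               valid = c(TRUE, TRUE, TRUE, FALSE)),
    toy_scores(c(g1 = 2, g2 = 1.5, g3 = 1.2, g4 = 0.4), "CARS")
  )
  gold <- toy_gold(c(g1 = TRUE, g2 = TRUE, g3 = FALSE, g4 = FALSE,
                     g9 = TRUE))
  expect_equal(sort(evaluation_universe(scores, gold, "PC")),
               c("g1", "g2", "g3"))          # constant-profile gene dropped
  expect_equal(sort(evaluation_universe(scores, gold, "CARS")),
               c("g1", "g2", "g3", "g4"))    # degenerate profiles retained
  nogold <- toy_gold(c(zz = TRUE, zy = FALSE))
  expect_error(evaluation_universe(scores, nogold, "PC"), "empty")
})

test_that("PR curve sweeps distinct thresholds with tied scores grouped", {
  sc <- c(a = 0.9, b = 0.8, c = 0.7, d = 0.6)
  lab <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  pr <- precision_recall_curve(sc, lab)
  expect_equal(pr$threshold, c(0.9, 0.8, 0.7, 0.6))
  expect_equal(pr$precision, c(1, 1, 2 / 3, 0.5))
  expect_equal(pr$recall, c(0.5, 1, 1, 1))
  expect_equal(pr$tp, c(1, 2, 2, 2))
  # precision at full recall equals the background fraction
  expect_equal(pr$precision[nrow(pr)], mean(lab))

  tie <- precision_recall_curve(c(a = 0.5, b = 0.5),
                                c(a = TRUE, b = FALSE))
  expect_equal(nrow(tie), 1L)
  expect_equal(tie$precision, 0.5)

  expect_error(precision_recall_curve(sc, lab > -1), "both")
})

test_that("recall is non-decreasing as the threshold falls", {
  set.seed(8)
  sc <- stats::setNames(runif(40), paste0("g", 1:40))
  lab <- stats::setNames(runif(40) < 0.4, names(sc))
  pr <- precision_recall_curve(sc, lab)
  expect_true(all(diff(pr$recall) >= 0))
  expect_true(all(diff(pr$threshold) < 0))
})

test_that("fold-precision threshold picks the largest qualifying set", {
  sc <- c(a = 0.9, b = 0.8, c = 0.7, d = 0.6)
  lab <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)   # f = 0.5
  thr <- select_threshold(sc, lab, "fold_precision", fold = 1.5)
  expect_equal(thr$threshold, 0.8)     # need precision >= 0.75
  expect_equal(thr$n_predicted, 2L)
  expect_equal(thr$precision, 1)
  expect_error(select_threshold(sc, lab, "fold_precision", fold = 2.5),
               "unreachable")          # 2.5 * 0.5 > 1
  bad <- c(a = 0.1, b = 0.9, c = 0.8, d = 0.7)
  expect_error(
    select_threshold(bad, c(a = TRUE, b = FALSE, c = FALSE, d = FALSE),
                     "fold_precision", fold = 1.5),
    "unreachable")                     # no cut attains 0.375... precision
})

test_that("top-fraction threshold selects ceil(q N) genes, ties included", {
  sc <- stats::setNames(seq(0.001, 0.5, by = 0.001), paste0("g", 1:500))
  thr <- select_threshold(sc, mode = "top_fraction", fraction = 0.01)
  expect_equal(thr$n_predicted, 5L)    # ceil(0.01 * 500)
  expect_equal(sum(sc >= thr$threshold), 5L)

  tied <- c(a = 0.9, b = 0.5, c = 0.5, d = 0.5, e = 0.1)
  thr2 <- select_threshold(tied, mode = "top_fraction", fraction = 0.4)
  expect_equal(thr2$threshold, 0.5)    # ceil(2) -> boundary ties all enter
  expect_equal(thr2$n_predicted, 4L)
})

test_that("genome-wide prediction is consistent with the learned cut", {
  scores <- toy_scores(c(g1 = .9, g2 = .8, g3 = .7, g4 = .6, g5 = .95), "PC")
  gold <- toy_gold(c(g1 = TRUE, g2 = TRUE, g3 = FALSE, g4 = FALSE))
  universe <- evaluation_universe(scores, gold, "PC")
  sc <- stats::setNames(scores$score, scores$gene_id)[universe]
  thr <- select_threshold(sc, gold$labels[universe], "fold_precision",
                          fold = 1.5)
  set <- predict_targets(scores, "PC", thr$threshold)
  # threshold learned on the universe applies to every scored gene (g5 has
  # no knockdown data but qualifies)
  expect_true("g5" %in% set$gene_id)
  expect_equal(intersect(set$gene_id, universe),
               names(sc)[sc >= thr$threshold])
  # degenerate cuts
  expect_equal(nrow(predict_targets(scores, "PC", 2)), 0L)
  expect_equal(nrow(predict_targets(scores, "PC", 0)), 5L)
})

test_that("union of methods keeps provenance and dominates member sets", {
  s1 <- predict_targets(toy_scores(c(g1 = .9, g2 = .8), "PC"), "PC", 0.5)
  s2 <- predict_targets(toy_scores(c(g2 = .7, g3 = .6), "SC",
                                   sign = c("-", "+")), "SC", 0.5)
  u <- union_of_methods(list(s1, s2))
  expect_equal(nrow(u), 3L)
  expect_gte(nrow(u), max(nrow(s1), nrow(s2)))
  g2 <- u[u$gene_id == "g2", ]
  expect_equal(g2$method, "PC,SC")
  expect_equal(g2$sign, "+,-")
  expect_equal(g2$n_methods, 2L)
  # disjoint sets add; identical sets collapse
  expect_equal(nrow(union_of_methods(list(s1, s1))), nrow(s1))
})

test_that("hypergeometric p matches closed form on the worked example", {
  gold <- toy_gold(c(g1 = TRUE, g2 = TRUE, g3 = FALSE, g4 = FALSE))
  universe <- paste0("g", 1:4)
  enr <- hypergeometric_enrichment(c("g1", "g2"), gold, universe)
  expect_equal(enr$p_value, 1 / choose(4, 2))   # all draws enumerated: 1/6
  expect_equal(enr$k, 2L)
  # predicted = universe forces the overlap: p = 1
  expect_equal(hypergeometric_enrichment(universe, gold, universe)$p_value, 1)
  # zero overlap: P[X >= 0] = 1
  expect_equal(hypergeometric_enrichment(c("g3", "g4"), gold,
                                         universe)$p_value, 1)
  expect_warning(
    p0 <- hypergeometric_enrichment(character(0), gold, universe),
    "empty")
  expect_equal(p0$p_value, 1)
})

test_that("sign summary partitions signed targets and skips MB", {
  set <- structure(
    data.frame(gene_id = paste0("g", 1:5),
               method = c("PC", "PC", "PC", "MB", "MB"),
               score = c(.9, .8, .7, 3, 2),
               sign = c("+", "+", "-", "n/a", "n/a")),
    class = c("target_set", "data.frame"))
  ss <- sign_summary(set)
  expect_equal(ss$positive[ss$method == "PC"], 2L)
  expect_equal(ss$negative[ss$method == "PC"], 1L)
  expect_false("MB" %in% ss$method)
})

test_that("stratified evaluation restricts the universe coherently", {
  set.seed(33)
  genes <- sprintf("g%02d", 1:40)
  scores <- toy_scores(stats::setNames(runif(40), genes), "PC")
  gold <- toy_gold(stats::setNames(runif(40) < 0.5, genes))
  full <- stratified_evaluation(scores, gold, "PC", genes, fold = 1.2)
  expect_equal(sort(full$universe), sort(genes))   # subset = universe

  half_a <- genes[1:20]; half_b <- genes[21:40]
  ea <- stratified_evaluation(scores, gold, "PC", half_a, fold = 1.01)
  eb <- stratified_evaluation(scores, gold, "PC", half_b, fold = 1.01)
  expect_true(all(ea$universe %in% half_a))
  # complementary strata partition the gold positives
  expect_equal(ea$enrichment$K + eb$enrichment$K, full$enrichment$K)
  expect_error(stratified_evaluation(scores, gold, "PC", c("zz1", "zz2")),
               "intersect")
})
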