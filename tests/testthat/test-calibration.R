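test_that("shuffling preserves degrees and avoids the original edges", {
  set.seed(3)
  for (rep in 1:20) {
    g <- random_bigraph(15, 20, 30)
    gs <- shuffle_bigraph(g, seed = rep)
    expect_equal(bigraph_degrees(gs, "left"), bigraph_degrees(g, "left"))
    expect_equal(bigraph_degrees(gs, "right"), bigraph_degrees(g, "right"))
    expect_equal(nrow(gs$edges), nrow(g$edges))
    expect_length(intersect(edge_keys(gs$edges$left, gs$edges$right),
                            edge_keys(g$edges$left, g$edges$right)), 0)
  }
})

test_that("two-edge graph shuffles to its unique disjoint rearrangement", {
  g <- bigraph(data.frame(l = c("x1", "x2"), r = c("z1", "z2")))
  # the only degree-preserving edge set disjoint from the original
  gs <- shuffle_bigraph(g, seed = 5)
  expect_setequal(edge_keys(gs$edges$left, gs$edges$right),
                  edge_keys(c("x1", "x2"), c("z2", "z1")))
})

test_that("complete bipartite graphs are reported infeasible", {
  k22 <- bigraph(expand.grid(l = c("x1", "x2"), r = c("z1", "z2"),
                             stringsAsFactors = FALSE))
  expect_error(shuffle_bigraph(k22, seed = 1),
               class = "codac_shuffle_infeasible")
  # a right item adjacent to every left item forces overlap too
  g <- bigraph(data.frame(l = c("x1", "x2", "x1"), r = c("z1", "z1", "z2")))
  expect_error(shuffle_bigraph(g, seed = 1),
               class = "codac_shuffle_infeasible")
})

test_that("shuffling is deterministic given the seed", {
  g <- random_bigraph(15, 20, 35)
  a <- shuffle_bigraph(g, seed = 99)
  b <- shuffle_bigraph(g, seed = 99)
  expect_identical(a$edges, b$edges)
})

test_that("gold standard sampling draws negatives from shuffled scores", {
  set.seed(21)
  g1 <- random_bigraph(12, 40, 120)
  g2 <- random_bigraph(12, 40, 120, lprefix = "y")
  sim <- cosine_similarity(build_biadjacency(g1), build_biadjacency(g2))
  e3 <- data.frame(x = c("x001", "x002", "x003"),
                   y = c("y001", "y002", "y003"))
  gs <- build_gold_standard(e3, sim, seed = 4)
  expect_equal(sum(gs$label == "P"), 3)
  expect_equal(sum(gs$label == "N"), 3)
  neg <- gs[gs$label == "N", ]
  expect_length(intersect(pair_keys(neg), pair_keys(e3)), 0)
  # negatives really carry nonzero shuffled-similarity scores
  expect_true(all(score_pairs(sim, neg) > 0))
  expect_identical(gs, build_gold_standard(e3, sim, seed = 4))
  expect_error(build_gold_standard(e3[0, ], sim, seed = 1), "empty")
  big_e3 <- data.frame(x = rep(paste0("q", 1:600), 2),
                       y = rep(paste0("r", 1:600), each = 2))
  expect_error(build_gold_standard(big_e3, sim, seed = 1),
               class = "codac_degenerate_calibration")
})

test_that("train/test split halves positives and negatives separately", {
  gs <- structure(data.frame(x = paste0("x", 1:201),
                             y = paste0("y", 1:201),
                             label = c(rep("P", 101), rep("N", 100))),
                  class = c("gold_standard", "data.frame"))
  sp <- split_gold_standard(gs, seed = 1)
  expect_equal(sum(sp$label == "P" & sp$split == "train"), 51)
  expect_equal(sum(sp$label == "P" & sp$split == "test"), 50)
  expect_equal(sum(sp$label == "N" & sp$split == "train"), 50)
  expect_identical(sp, split_gold_standard(gs, seed = 1))
})

test_that("threshold selection maximizes Training F-measure on the grid", {
  gs <- structure(data.frame(x = paste0("x", 1:8), y = paste0("y", 1:8),
                             label = rep(c("P", "N"), each = 4),
                             split = rep(c("train", "test"), 4)),
                  class = c("gold_standard", "data.frame"))
  scores <- data.frame(x = gs$x, y = gs$y,
                       score = c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.15, 0.05))
  cal <- select_threshold(scores, gs)
  expect_equal(cal$f_train, 1)
  # smallest grid threshold achieving F1 = 1 on training scores
  # {P: 0.9, 0.85; N: 0.1, 0.15}: strict > 0.15 already separates
  expect_equal(cal$threshold, 0.15)
  # test half {P: 0.8, 0.95; N: 0.2, 0.05}: 0.2 > 0.15 is one false
  # positive, so F1 = 2 * 1 * (2/3) / (1 + 2/3) = 0.8
  expect_equal(cal$f_test, 0.8, tolerance = 1e-12)

  # all scores tied at 0.5, one positive one negative per half:
  # any t < 0.5 predicts everything positive, F1 = 2/3
  gs2 <- structure(data.frame(x = paste0("x", 1:4), y = paste0("y", 1:4),
                              label = c("P", "N", "P", "N"),
                              split = c("train", "train", "test", "test")),
                   class = c("gold_standard", "data.frame"))
  sc2 <- data.frame(x = gs2$x, y = gs2$y, score = 0.5)
  cal2 <- select_threshold(sc2, gs2)
  expect_equal(cal2$f_train, 2 / 3, tolerance = 1e-12)
  expect_lt(cal2$threshold, 0.5)

  # positives scored 0: degenerate, flagged
  sc3 <- data.frame(x = gs2$x, y = gs2$y, score = 0)
  expect_warning(cal3 <- select_threshold(sc3, gs2), "degenerate")
  expect_equal(cal3$f_train, 0)
})

test_that("threshold selection agrees with the independent grid scan", {
  set.seed(13)
  for (rep in 1:20) {
    n <- 40
    lab <- rep(c("P", "N"), each = n / 2)
    score <- ifelse(lab == "P", rbeta(n, 4, 2), rbeta(n, 2, 4))
    split <- sample(rep(c("train", "test"), n / 2))
    gs <- structure(data.frame(x = paste0("x", 1:n), y = paste0("y", 1:n),
                               label = lab, split = split),
                    class = c("gold_standard", "data.frame"))
    sc <- data.frame(x = gs$x, y = gs$y, score = score)
    cal <- select_threshold(sc, gs)
    orc <- oracle_threshold(score, lab, split)
    expect_identical(cal$threshold, orc$threshold)
    expect_equal(cal$f_train, orc$f, tolerance = 1e-12)
  }
})

test_that("roc_auc equals pairwise Mann-Whitney counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "undefined")
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    score <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(score, pos), oracle_auc(score, pos),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with pROC on untied rankings", {
  skip_if_not_installed("pROC")
  set.seed(19)
  score <- runif(80)
  pos <- runif(80) < 0.3
  expect_equal(roc_auc(score, pos),
               as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("weight search handles degenerate and adversarial datasets", {
  mk_sim <- function(id, pairs, scores) {
    sim <- Matrix::sparseMatrix(
      i = match(pairs$x, sort(unique(pairs$x))),
      j = match(pairs$y, sort(unique(pairs$y))), x = scores,
      dimnames = list(sort(unique(pairs$x)), sort(unique(pairs$y))))
    structure(list(dataset_id = id, sim = sim), class = "dataset_similarity")
  }
  pairs <- data.frame(x = paste0("x", 1:10), y = paste0("y", 1:10))
  pos <- pairs[1:3, ]
  # single dataset: weight-invariant, returns the first grid point
  s1 <- mk_sim("a", pairs, c(0.9, 0.8, 0.7, runif(7, 0, 0.5)))
  w1 <- optimize_weights(list(s1), pos)
  expect_equal(unname(w1$weights), 1)
  expect_equal(w1$auc, 1)
  # identical matrices: consensus invariant, all weights stay 1.0
  w2 <- optimize_weights(list(s1, mk_sim("b", pairs, c(0.9, 0.8, 0.7,
                                                       s1$sim@x[4:10]))), pos)
  expect_equal(unname(w2$weights), c(1, 1))
  expect_error(optimize_weights(list(s1, s1, s1, s1), pos,
                                strategy = "exhaustive"), "3 datasets")
})

test_that("coordinate ascent matches exhaustive search on 2-dataset problems", {
  for (seed in 1:4) {
    inst <- two_dataset_sims(seed)
    ex <- optimize_weights(inst$sims, inst$positives,
                           strategy = "exhaustive")
    ca <- optimize_weights(inst$sims, inst$positives,
                           strategy = "coordinate_ascent")
    expect_equal(ca$auc, ex$auc, tolerance = 1e-12)
    expect_true(all(ca$weights %in% round(seq(1, 10, 0.1), 1)))
  }
})

test_that("filtering keeps strict exceedances and known pairs only", {
  sim <- Matrix::sparseMatrix(i = 1:3, j = 1:3, x = c(0.5, 0.3, 0.001),
                              dimnames = list(paste0("x", 1:3),
                                              paste0("y", 1:3)))
  cs <- structure(list(sim = sim, weights = c(d = 1)),
                  class = "consensus_similarity")
  e3 <- data.frame(x = "x3", y = "y3")
  f <- filter_similarity(cs, 0.3, e3)
  expect_equal(f$sim["x1", "y1"], 0.5)       # strictly above
  expect_equal(f$sim["x2", "y2"], 0)          # boundary: strict >
  expect_equal(f$sim["x3", "y3"], 0.001)      # kept because known
  # idempotent at the same threshold
  f2 <- filter_similarity(f, 0.3, e3)
  expect_equal(as.matrix(f2$sim), as.matrix(f$sim))
})
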