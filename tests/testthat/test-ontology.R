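test_that("ancestor queries follow the transitive is_a closure", {
  o <- ontology(data.frame(id = c("a", "b", "c", "d")),
                list(b = "a", c = "a", d = c("b", "c")))
  expect_equal(ancestors(o, "a"), character())
  expect_setequal(ancestors(o, "d"), c("a", "b", "c"))
  chain <- ontology(data.frame(id = c("a", "b", "c")),
                    list(b = "a", c = "b"))
  expect_setequal(ancestors(chain, "c"), c("a", "b"))
  expect_error(ancestors(o, "nope"), "unknown")
})

test_that("ancestors match igraph reachability on random rDAGs", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:15) {
    o <- random_rdag(sample(5:25, 1))
    for (t in sample(o$terms$id, 4))
      expect_setequal(ancestors(o, t), oracle_ancestors(o, t))
  }
})

test_that("cyclic parent relations are rejected at load time", {
  expect_error(ontology(data.frame(id = c("a", "b")),
                        list(a = "b", b = "a")), "cycle")
  expect_error(ontology(data.frame(id = "a"), list(a = "a")), "cycle")
  expect_error(ontology(data.frame(id = "a"), list(a = "ghost")), "unknown")
})

test_that("propagation adds ancestor edges restricted to the vocabulary", {
  o <- ontology(data.frame(id = c("x1", "x2", "x3")),
                list(x2 = "x1", x3 = "x2"))
  # x2 is a parent of x3: the (x2, z3) edge is added
  g <- bigraph(data.frame(l = "x3", r = "z3"),
               left_items = c("x2", "x3"), right_items = "z3")
  p <- propagate_ontology(g, o)
  expect_setequal(edge_keys(p$edges$left, p$edges$right),
                  edge_keys(c("x3", "x2"), c("z3", "z3")))
  # x1 is an ancestor but absent from the vocabulary: gains nothing
  expect_false("x1" %in% p$left_items)
  # already-closed graphs are fixed points
  expect_setequal(edge_keys(propagate_ontology(p, o)$edges$left,
                            propagate_ontology(p, o)$edges$right),
                  edge_keys(p$edges$left, p$edges$right))
})

test_that("propagation is idempotent and monotone on random rDAGs", {
  set.seed(37)
  for (rep in 1:20) {
    o <- random_rdag(12)
    g <- random_bigraph(8, 10, 20, lprefix = "q")
    # relabel left items as ontology terms
    g <- bigraph(data.frame(l = o$terms$id[match(g$edges$left,
                                                 g$left_items)],
                            r = g$edges$right),
                 left_items = o$terms$id[1:8], right_items = g$right_items)
    p1 <- propagate_ontology(g, o)
    p2 <- propagate_ontology(p1, o)
    k0 <- edge_keys(g$edges$left, g$edges$right)
    k1 <- edge_keys(p1$edges$left, p1$edges$right)
    expect_true(all(k0 %in% k1))
    expect_setequal(edge_keys(p2$edges$left, p2$edges$right), k1)
  }
})

test_that("most-specific filter returns the per-y antichain", {
  o <- ontology(data.frame(id = c("x1", "x2", "x3", "u")),
                list(x2 = "x1", x3 = "x2"))
  expect_equal(most_specific_filter(
    data.frame(x = c("x1", "x3"), y = "y1"), o)$x, "x3")
  # full chain paired with one y collapses to the leaf
  expect_equal(most_specific_filter(
    data.frame(x = c("x1", "x2", "x3"), y = "y1"), o)$x, "x3")
  # unrelated terms pass through
  un <- data.frame(x = c("x3", "u"), y = c("y1", "y1"))
  expect_equal(nrow(most_specific_filter(un, o)), 2)
  # the filter is per-y: the same parent survives with a different y
  mixed <- data.frame(x = c("x1", "x3", "x1"), y = c("y1", "y1", "y2"))
  ms <- most_specific_filter(mixed, o)
  expect_setequal(pair_keys(ms), pair_keys(data.frame(x = c("x3", "x1"),
                                                      y = c("y1", "y2"))))
})

test_that("most-specific filter agrees with brute-force closure oracle", {
  set.seed(41)
  for (rep in 1:15) {
    o <- random_rdag(15)
    assocs <- unique(data.frame(
      x = sample(o$terms$id, 30, replace = TRUE),
      y = sample(paste0("y", 1:5), 30, replace = TRUE)))
    ms <- most_specific_filter(assocs, o)
    # oracle: drop (x,y) iff x is an ancestor of another x' with the same y
    keep <- vapply(seq_len(nrow(assocs)), function(i) {
      others <- assocs$x[assocs$y == assocs$y[i] & assocs$x != assocs$x[i]]
      !any(vapply(others, function(x2)
        assocs$x[i] %in% ancestors(o, x2), logical(1)))
    }, logical(1))
    expect_setequal(pair_keys(ms), pair_keys(assocs[keep, ]))
  }
})

test_that("OBO round trip preserves terms, parents and namespaces", {
  o <- ontology(data.frame(id = c("T:1", "T:2", "T:3"),
                           name = c("root", "mid", "leaf"),
                           namespace = "ns1"),
                list(`T:2` = "T:1", `T:3` = "T:2"))
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(o, path)
  o2 <- read_obo(path)
  expect_setequal(o2$terms$id, o$terms$id)
  expect_equal(o2$parents[["T:3"]], "T:2")
  expect_equal(o2$terms$name[o2$terms$id == "T:2"], "mid")
})

test_that("OBO loader drops obsolete terms and enforces single namespace", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: A:1", "name: rootA", "namespace: nsA", "",
               "[Term]", "id: A:2", "name: child", "namespace: nsA",
               "is_a: A:1 ! rootA", "",
               "[Term]", "id: B:1", "name: rootB", "namespace: nsB", "",
               "[Term]", "id: A:9", "name: gone", "namespace: nsA",
               "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), path)
  expect_message(o <- read_obo(path, namespace = "nsA"), "obsolete")
  expect_setequal(o$terms$id, c("A:1", "A:2"))
  # cross-namespace is_a fails when restricted
  writeLines(c("[Term]", "id: A:1", "namespace: nsA", "is_a: B:1", "",
               "[Term]", "id: B:1", "namespace: nsB"), path)
  expect_error(read_obo(path, namespace = "nsA"), "cross")
})
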