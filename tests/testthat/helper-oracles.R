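# Independent brute-force oracles and random-input generators used across
# the suite. Every oracle works from first principles (set arithmetic,
# exhaustive enumeration, pairwise counting) and never calls the code path
# it checks.

random_bigraph <- function(n_l, n_r, n_edges,
                           lprefix = "x", rprefix = "z") {
  li <- sprintf("%s%03d", lprefix, seq_len(n_l))
  ri <- sprintf("%s%03d", rprefix, seq_len(n_r))
  idx <- sample.int(n_l * n_r, min(n_edges, n_l * n_r))
  bigraph(data.frame(left = li[((idx - 1) %% n_l) + 1],
                     right = ri[((idx - 1) %/% n_l) + 1]),
          left_items = li, right_items = ri)
}

# neighbour sets of every left item, over the full left vocabulary
neighbour_sets <- function(g) {
  sets <- split(g$edges$right, factor(g$edges$left, levels = g$left_items))
  lapply(sets, unique)
}

# cosine by set arithmetic: |N(x) inter N(y)| / sqrt(|N(x)| |N(y)|)
oracle_cosine <- function(g1, g2) {
  n1 <- neighbour_sets(g1); n2 <- neighbour_sets(g2)
  out <- matrix(0, length(n1), length(n2),
                dimnames = list(g1$left_items, g2$left_items))
  for (x in g1$left_items) for (y in g2$left_items) {
    a <- n1[[x]]; b <- n2[[y]]
    if (length(a) > 0 && length(b) > 0)
      out[x, y] <- length(intersect(a, b)) / sqrt(length(a) * length(b))
  }
  out
}

# hypergeometric upper tail by exhaustive enumeration of all C(n_z, n_y)
# equiprobable neighbour sets of y, with x fixed to items 1..n_x
oracle_hyper <- function(n_z, n_x, n_y, k) {
  sets <- utils::combn(n_z, n_y)
  hits <- apply(sets, 2, function(s) sum(s <= n_x) >= k)
  mean(hits)
}

# independent full-grid threshold scan
oracle_threshold <- function(score, label, split) {
  grid <- round(seq(0, 1, by = 0.001), 3)
  s <- score[split == "train"]; pos <- label[split == "train"] == "P"
  f <- vapply(grid, function(t) {
    tp <- sum(s > t & pos); fp <- sum(s > t & !pos)
    r <- tp / sum(pos)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    if (p + r > 0) 2 * r * p / (p + r) else 0
  }, numeric(1))
  list(threshold = grid[which.max(f)], f = max(f))
}

# Mann-Whitney AUC by explicit pairwise counting (0.5 credit for ties)
oracle_auc <- function(score, positive) {
  sp <- score[positive]; sb <- score[!positive]
  wins <- 0
  for (a in sp) wins <- wins + sum(a > sb) + 0.5 * sum(a == sb)
  wins / (length(sp) * length(sb))
}

# random rooted DAG: term i > 1 gets 1-2 parents among earlier terms
random_rdag <- function(n_terms) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- list()
  for (i in seq_len(n_terms)[-1]) {
    k <- sample(1:min(2, i - 1), 1)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], k)
  }
  ontology(data.frame(id = ids, name = ids, namespace = "test"), parents)
}

# ancestor set by reachability over the parent edge list (igraph)
oracle_ancestors <- function(o, term) {
  edges <- do.call(rbind, lapply(names(o$parents), function(ch)
    cbind(ch, o$parents[[ch]])))
  if (is.null(edges)) return(character())
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!term %in% igraph::V(g)$name) return(character())
  reach <- igraph::subcomponent(g, term, mode = "out")$name
  sort(setdiff(reach, term))
}

# collapse a bigraph's right identifiers through a cluster map by plain set
# operations (oracle for cluster_common_items)
oracle_collapse <- function(g, cm) {
  e <- unique(data.frame(left = g$edges$left,
                         right = unname(cm[g$edges$right])))
  e
}

pair_keys <- function(df) paste(df$x, df$y, sep = "\r")

# 2-dataset synthetic instance (heterogeneous quality) for weight-search checks
two_dataset_sims <- function(seed, quality = c(1, 0.6)) {
  fix <- generate_tripartite(synthetic_spec(
    n_x = 20, n_y = 20, n_z = 200, n_planted = 20, n_datasets = 2,
    dataset_quality = quality, seed = seed))
  sims <- lapply(names(fix$datasets), function(id) {
    cg <- fix$datasets[[id]]
    z <- cg$g1$right_items
    cosine_similarity(build_biadjacency(cg$g1, z),
                      build_biadjacency(cg$g2, z), id)
  })
  list(sims = sims, positives = fix$e3_given)
}

# exact feasibility of a degree-preserving rearrangement disjoint from the
# original edges, via max-flow with the original cells forbidden
oracle_shuffle_feasible <- function(g) {
  ld <- bigraph_degrees(g, "left"); rd <- bigraph_degrees(g, "right")
  m <- nrow(g$edges)
  orig <- paste(g$edges$left, g$edges$right)
  el <- character(); caps <- numeric()
  for (i in names(ld)) { el <- c(el, "s", i); caps <- c(caps, ld[i]) }
  for (j in names(rd)) { el <- c(el, j, "t"); caps <- c(caps, rd[j]) }
  for (i in names(ld)) for (j in names(rd))
    if (!(paste(i, j) %in% orig)) { el <- c(el, i, j); caps <- c(caps, 1) }
  gr <- igraph::graph_from_edgelist(matrix(el, ncol = 2, byrow = TRUE))
  igraph::max_flow(gr, "s", "t", capacity = caps)$value == m
}
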