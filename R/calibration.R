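# Gold-standard construction, threshold selection, and weight optimization.
#
# Calibration never sees ground truth beyond the known-association edge set
# E3: negatives come from scoring degree-preserving shuffled copies of the
# evidence layers, so the decision threshold reflects what common-neighbour
# similarity looks like under a null that keeps every node's connectivity.

abort_with_class <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "codac_error")))
}

#' Degree-preserving edge shuffle of a bigraph
#'
#' Produces a random bigraph with exactly the original per-node left and
#' right degrees, the original edge count, and zero edges in common with the
#' input. Implemented as repeated random double-edge swaps (which preserve
#' degrees by construction), followed by targeted swaps that remove any
#' residual overlap with the original edges; if overlap cannot be cleared the
#' whole shuffle restarts, up to `max_tries` times.
#'
#' @param g a [bigraph()] with at least 2 edges
#' @param seed integer seed; the result is deterministic given the seed
#' @param max_tries maximum number of restarts before giving up
#' @return a shuffled [bigraph()] over the same vocabularies
#' @section Errors: provable infeasibility (e.g. a complete bipartite graph,
#'   where every degree-preserving rearrangement equals the original) raises
#'   a condition of class `codac_shuffle_infeasible`; running out of tries
#'   raises `codac_shuffle_exhausted`. Both inherit `codac_shuffle_failure`.
#' @export
shuffle_bigraph <- function(g, seed, max_tries = 100L) {
  stopifnot(inherits(g, "bigraph"))
  m <- nrow(g$edges)
  if (m < 2) stop("shuffle requires at least 2 edges")
  li0 <- match(g$edges$left, g$left_items)
  ri0 <- match(g$edges$right, g$right_items)
  nR <- length(g$right_items)
  ldeg <- tabulate(li0, nbins = length(g$left_items))
  rdeg <- tabulate(ri0, nbins = nR)
  n_lpos <- sum(ldeg > 0)
  n_rpos <- sum(rdeg > 0)
  # provable infeasibility: complete bipartite on the positive-degree
  # support, or a node already adjacent to every positive-degree partner --
  # any degree-preserving graph must then reuse original edges
  if (m == n_lpos * n_rpos || any(ldeg == n_rpos) || any(rdeg == n_lpos))
    abort_with_class(
      "no degree-preserving edge set disjoint from the original exists",
      c("codac_shuffle_infeasible", "codac_shuffle_failure"))
  key <- function(l, r) (l - 1) * nR + r
  orig <- key(li0, ri0)
  in_orig <- logical(length(g$left_items) * nR)
  in_orig[orig] <- TRUE
  res <- withr::with_seed(seed, {
    result <- NULL
    for (try in seq_len(max_tries)) {
      li <- li0; ri <- ri0
      present <- logical(length(in_orig))
      present[key(li, ri)] <- TRUE
      do_swap <- function(a, b) {
        # swap the right endpoints of edges a and b if no duplicate arises
        if (li[a] == li[b] || ri[a] == ri[b]) return(FALSE)
        k_old_a <- key(li[a], ri[a]); k_old_b <- key(li[b], ri[b])
        k_new_a <- key(li[a], ri[b]); k_new_b <- key(li[b], ri[a])
        if (present[k_new_a] || present[k_new_b]) return(FALSE)
        present[k_old_a] <<- FALSE; present[k_old_b] <<- FALSE
        present[k_new_a] <<- TRUE; present[k_new_b] <<- TRUE
        tmp <- ri[a]; ri[a] <<- ri[b]; ri[b] <<- tmp
        TRUE
      }
      for (s in seq_len(10L * m)) {
        ab <- sample.int(m, 2)
        do_swap(ab[1], ab[2])
      }
      # clear residual overlap: swap an overlapping edge with a random edge,
      # accepting moves that do not increase the overlap count, plus
      # occasional uphill moves to escape local minima of the walk
      for (s in seq_len(200L * m)) {
        ov <- which(in_orig[key(li, ri)])
        if (length(ov) == 0) break
        a <- ov[sample.int(length(ov), 1)]
        b <- sample.int(m, 1)
        if (a == b) next
        before <- in_orig[key(li[a], ri[a])] + in_orig[key(li[b], ri[b])]
        after <- in_orig[key(li[a], ri[b])] + in_orig[key(li[b], ri[a])]
        if (after <= before || stats::runif(1) < 0.25) do_swap(a, b)
      }
      if (!any(in_orig[key(li, ri)])) {
        result <- list(li = li, ri = ri)
        break
      }
    }
    result
  })
  if (is.null(res))
    abort_with_class(
      sprintf("could not find a non-overlapping shuffle in %d tries", max_tries),
      c("codac_shuffle_exhausted", "codac_shuffle_failure"))
  bigraph(data.frame(left = g$left_items[res$li],
                     right = g$right_items[res$ri],
                     stringsAsFactors = FALSE),
          left_items = g$left_items, right_items = g$right_items)
}

#' Build the gold standard of positive and negative association examples
#'
#' Positives are the known associations E3. Negatives are |E3| pairs sampled
#' uniformly without replacement from the nonzero entries of the similarity
#' matrix computed on the shuffled evidence layers, excluding any pair that
#' is itself a known association: they are pairs that *look* associated under
#' the degree-preserving null.
#'
#' @param e3 data frame of known (x, y) associations (columns `x`, `y`, or
#'   the first two columns)
#' @param shuffled_sim `dataset_similarity` or `consensus_similarity`
#'   computed from shuffled bigraphs
#' @param seed integer seed for negative sampling
#' @return an object of class `gold_standard`: data frame with columns `x`,
#'   `y`, `label` (`"P"`/`"N"`), initially without a train/test split
#' @export
build_gold_standard <- function(e3, shuffled_sim, seed) {
  e3 <- as_pairs(e3)
  if (nrow(e3) == 0) stop("no positives to calibrate: E3 is empty")
  cand <- similarity_entries(
    if (inherits(shuffled_sim, c("dataset_similarity", "consensus_similarity")))
      shuffled_sim$sim else shuffled_sim)
  pos_keys <- edge_keys(e3$x, e3$y)
  cand <- cand[!(edge_keys(cand$x, cand$y) %in% pos_keys), , drop = FALSE]
  n_p <- nrow(e3)
  if (nrow(cand) < n_p)
    abort_with_class(
      sprintf("only %d eligible shuffled pairs for %d required negatives",
              nrow(cand), n_p),
      "codac_degenerate_calibration")
  idx <- withr::with_seed(seed, sample.int(nrow(cand), n_p))
  neg <- cand[idx, c("x", "y")]
  gs <- rbind(data.frame(x = e3$x, y = e3$y, label = "P",
                         stringsAsFactors = FALSE),
              data.frame(x = neg$x, y = neg$y, label = "N",
                         stringsAsFactors = FALSE))
  rownames(gs) <- NULL
  structure(gs, class = c("gold_standard", "data.frame"))
}

# internal: coerce a 2-column object to a unique (x, y) pair data frame
as_pairs <- function(p) {
  p <- as.data.frame(p, stringsAsFactors = FALSE)
  if (nrow(p) == 0)
    return(data.frame(x = character(), y = character(),
                      stringsAsFactors = FALSE))
  if (!all(c("x", "y") %in% names(p))) names(p)[1:2] <- c("x", "y")
  unique(data.frame(x = as.character(p$x), y = as.character(p$y),
                    stringsAsFactors = FALSE))
}

#' Split a gold standard into Training and Test halves
#'
#' Positives and negatives are each split separately so both halves preserve
#' the positive:negative ratio. With an odd count the Training half receives
#' the extra example (ceiling convention).
#'
#' @param gs a [build_gold_standard()] result
#' @param seed integer seed
#' @return the gold standard with an added `split` column
#'   (`"train"`/`"test"`)
#' @export
split_gold_standard <- function(gs, seed) {
  stopifnot(inherits(gs, "gold_standard"))
  n_p <- sum(gs$label == "P"); n_n <- sum(gs$label == "N")
  if (n_p < 2 || n_n < 2)
    stop("need at least 2 positives and 2 negatives to split")
  gs$split <- NA_character_
  withr::with_seed(seed, {
    for (lab in c("P", "N")) {
      idx <- which(gs$label == lab)
      tr <- sample(idx, ceiling(length(idx) / 2))
      gs$split[tr] <- "train"
      gs$split[setdiff(idx, tr)] <- "test"
    }
  })
  gs
}

#' Select the similarity score threshold by Training-half F-measure
#'
#' Scans thresholds t over the grid 0.000, 0.001, ..., 1.000. A pair is
#' predicted positive iff its score is strictly greater than t. For each t
#' the recall R = TP/(TP+FN), precision P = TP/(TP+FP) and F-measure
#' F1 = 2RP/(P+R) are computed on the Training half; the smallest t
#' maximizing Training F1 is returned, together with the Test-half F1 at
#' that t as an independent check. Gold-standard pairs without a score are
#' scored 0.
#'
#' @param scores a similarity object or a data frame with columns `x`, `y`,
#'   `score`
#' @param gs a split gold standard (see [split_gold_standard()])
#' @return object of class `calibration_result`: list with `threshold`,
#'   `f_train`, `f_test`, `precision`, `recall` (training values at the
#'   selected threshold)
#' @export
select_threshold <- function(scores, gs) {
  stopifnot(inherits(gs, "gold_standard"))
  if (is.null(gs$split)) stop("gold standard has no train/test split")
  s <- lookup_scores(scores, gs)
  grid <- round(seq(0, 1, by = 0.001), 3)
  f_half <- function(mask) {
    sv <- s[mask]; pos <- gs$label[mask] == "P"
    if (!any(pos)) abort_with_class("no positives in this gold-standard half",
                                    "codac_degenerate_calibration")
    n_pos <- sum(pos)
    function(t) {
      pred <- sv > t
      tp <- sum(pred & pos); fp <- sum(pred & !pos)
      r <- tp / n_pos
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      f <- if (p + r > 0) 2 * r * p / (p + r) else 0
      c(f = f, p = p, r = r)
    }
  }
  train_eval <- f_half(gs$split == "train")
  f_tr <- vapply(grid, function(t) train_eval(t)[["f"]], numeric(1))
  best <- which.max(f_tr)  # first maximum = smallest threshold
  t_star <- grid[best]
  at_best <- train_eval(t_star)
  if (f_tr[best] == 0)
    warning("degenerate calibration: best Training F-measure is 0")
  f_te <- f_half(gs$split == "test")(t_star)[["f"]]
  structure(list(threshold = t_star, f_train = unname(f_tr[best]),
                 f_test = unname(f_te),
                 precision = unname(at_best[["p"]]),
                 recall = unname(at_best[["r"]])),
            class = "calibration_result")
}

# internal: scores for gold-standard pairs, from a similarity object or an
# (x, y, score) data frame; absent pairs score 0
lookup_scores <- function(scores, pairs) {
  if (inherits(scores, c("dataset_similarity", "consensus_similarity")) ||
      methods::is(scores, "Matrix"))
    return(score_pairs(scores, pairs))
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "score") %in% names(scores)))
  i <- match(edge_keys(pairs$x, pairs$y), edge_keys(scores$x, scores$y))
  ifelse(is.na(i), 0, scores$score[i])
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: threshold %.3f, F1 train %.3f / test %.3f (P %.3f, R %.3f)\n",
    x$threshold, x$f_train, x$f_test, x$precision, x$recall))
  invisible(x)
}

#' Area under the ROC curve of a score ranking
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' outranks a uniformly chosen background item, with ties credited 0.5
#' (midranks).
#'
#' @param score numeric vector of scores
#' @param positive logical vector, `TRUE` for the relevant class
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  n_pos <- sum(positive); n_bg <- sum(!positive)
  if (n_pos == 0 || n_bg == 0)
    stop("AUC undefined: need at least one positive and one background score")
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_bg)
}

#' Optimize per-dataset consensus weights by ROC-AUC
#'
#' Each dataset weight ranges over the grid 1.0, 1.1, ..., 10.0. For a
#' candidate weight vector, the consensus score of every computed pair is
#' ranked and the AUC of retrieving the known-positive pairs against all
#' other computed pairs (the background) is measured; positives that no
#' dataset scored enter the ranking with score 0. The weight combination
#' with the largest AUC wins.
#'
#' `exhaustive` enumerates the full grid (only allowed for up to 3 datasets).
#' `coordinate_ascent` (default) sweeps one weight at a time over the grid
#' in dataset input order, moving to the first grid value that strictly
#' improves the AUC (ties keep the current weight), cycling until a full
#' sweep makes no improvement (at most 20 cycles). The sweep is restarted
#' from a deterministic set of starting points — all-equal weights, then one
#' dataset-dominant start (that weight 10, the rest 1) per dataset — and the
#' best final AUC wins (earliest start on ties); the plain single-start
#' ascent can stall in local maxima of the jagged AUC landscape that these
#' extra starts escape.
#'
#' @param sims list of `dataset_similarity` objects
#' @param positives data frame of known (x, y) associations
#' @param strategy `"coordinate_ascent"` or `"exhaustive"`
#' @return object of class `weight_search_result`: list with `weights`
#'   (named numeric) and `auc`
#' @export
optimize_weights <- function(sims, positives,
                             strategy = c("coordinate_ascent", "exhaustive")) {
  strategy <- match.arg(strategy)
  if (length(sims) == 0) stop("at least one dataset is required")
  positives <- as_pairs(positives)
  if (nrow(positives) == 0) stop("positives must be nonempty")
  ids <- vapply(sims, function(s) s$dataset_id, character(1))
  d <- length(sims)
  ents <- lapply(sims, function(s) similarity_entries(s$sim))
  pair_keys <- unique(c(unlist(lapply(ents, function(e) edge_keys(e$x, e$y))),
                        edge_keys(positives$x, positives$y)))
  S <- matrix(0, nrow = length(pair_keys), ncol = d)
  for (k in seq_len(d)) {
    i <- match(edge_keys(ents[[k]]$x, ents[[k]]$y), pair_keys)
    S[i, k] <- ents[[k]]$score
  }
  pos <- pair_keys %in% edge_keys(positives$x, positives$y)
  if (all(pos))
    stop("no background pairs: every computed pair is a known positive")
  grid <- round(seq(1, 10, by = 0.1), 1)
  auc_of <- function(v) roc_auc(v, pos)
  if (strategy == "exhaustive") {
    if (d > 3)
      stop("exhaustive search over ", length(grid), "^", d,
           " combinations is not permitted for more than 3 datasets; ",
           "use coordinate_ascent")
    W <- as.matrix(expand.grid(rep(list(grid), d)))
    best_auc <- -Inf; best_i <- 1L
    chunk <- 500L
    for (start in seq(1L, nrow(W), by = chunk)) {
      rows <- start:min(start + chunk - 1L, nrow(W))
      sc <- S %*% t(W[rows, , drop = FALSE])
      aucs <- apply(sc, 2, auc_of)
      j <- which.max(aucs)
      if (aucs[j] > best_auc + 1e-12) {
        best_auc <- aucs[j]; best_i <- rows[j]
      }
    }
    w <- W[best_i, ]
  } else {
    ascend <- function(w) {
      best <- auc_of(S %*% w)
      for (cycle in seq_len(20L)) {
        improved <- FALSE
        for (j in seq_len(d)) {
          base <- if (d > 1) S[, -j, drop = FALSE] %*% w[-j] else
            numeric(nrow(S))
          sc <- as.numeric(base) + outer(S[, j], grid)
          aucs <- apply(sc, 2, auc_of)
          k <- which.max(aucs)  # first maximum
          if (aucs[k] > best + 1e-12) {
            w[j] <- grid[k]; best <- aucs[k]; improved <- TRUE
          }
        }
        if (!improved) break
      }
      list(w = w, auc = best)
    }
    starts <- c(list(rep(1, d)),
                lapply(seq_len(d), function(j) replace(rep(1, d), j, 10)))
    best_auc <- -Inf; w <- rep(1, d)
    for (w0 in starts) {
      res <- ascend(w0)
      if (res$auc > best_auc + 1e-12) {
        best_auc <- res$auc; w <- res$w
      }
    }
  }
  structure(list(weights = stats::setNames(round(w, 1), ids),
                 auc = unname(best_auc)),
            class = "weight_search_result")
}

#' @export
print.weight_search_result <- function(x, ...) {
  cat(sprintf("weight_search_result: AUC %.4f; %s\n", x$auc,
              paste(sprintf("%s=%.1f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Filter a consensus similarity matrix at the calibrated threshold
#'
#' An entry survives iff its score is strictly greater than `t`, or the pair
#' is a known association (which is kept at its computed score however small,
#' and flagged as known downstream). Everything else is zeroed. The result is
#' the weighted biadjacency matrix of the enriched association graph.
#'
#' @param cs a `consensus_similarity` (or `dataset_similarity`)
#' @param t threshold in \[0, 1\]
#' @param e3 data frame of known (x, y) associations
#' @return a filtered object of the same class, with attribute `threshold`
#' @export
filter_similarity <- function(cs, t, e3) {
  stopifnot(t >= 0, t <= 1)
  e3 <- as_pairs(e3)
  sim <- cs$sim
  tr <- Matrix::summary(methods::as(sim, "TsparseMatrix"))
  known <- edge_keys(rownames(sim)[tr$i], colnames(sim)[tr$j]) %in%
    edge_keys(e3$x, e3$y)
  keep <- tr$x > t | known
  out <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep],
                              dims = dim(sim), dimnames = dimnames(sim))
  res <- cs
  res$sim <- methods::as(out, "CsparseMatrix")
  attr(res, "threshold") <- t
  res
}

#' Write a gold standard as TSV
#'
#' Columns: `x_id`, `y_id`, `label` (P/N), `split` (train/test).
#'
#' @param gs a split gold standard
#' @param path output path
#' @export
write_gold_standard_tsv <- function(gs, path) {
  df <- as.data.frame(gs)[, c("x", "y", "label", "split")]
  df <- df[order(df$label, df$x, df$y), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("x_id", "y_id", "label", "split"))
  invisible(path)
}
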