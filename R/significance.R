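# Hypergeometric significance of predicted edges, Bonferroni correction,
# and the Gold/Silver/Bronze quality classes.

#' Hypergeometric p-value of a common-neighbour count
#'
#' Probability that x (with `n_x` neighbours among `n_z` items) and y (with
#' `n_y` neighbours) share at least `k_xy` common neighbours by chance:
#' p(K >= k_xy) = sum_{v=k_xy}^{min(n_x,n_y)} C(n_x,v) C(n_z-n_x,n_y-v) /
#' C(n_z,n_y). Computed through the hypergeometric survival function, which
#' is numerically safe for common-neighbour universes up to 1e7 items.
#'
#' Arguments are vectorized (recycled to a common length).
#'
#' @param n_z total number of common-neighbour (Z) items
#' @param n_x,n_y neighbour counts of x and y in Z
#' @param k_xy observed number of common neighbours
#' @return upper-tail p-value(s) in \[0, 1\]; `k_xy = 0` gives exactly 1
#' @export
hypergeometric_pvalue <- function(n_z, n_x, n_y, k_xy) {
  n <- max(length(n_z), length(n_x), length(n_y), length(k_xy))
  n_z <- rep_len(n_z, n); n_x <- rep_len(n_x, n)
  n_y <- rep_len(n_y, n); k_xy <- rep_len(k_xy, n)
  if (any(n_z < 1)) stop("n_z must be >= 1")
  if (any(n_x > n_z) || any(n_y > n_z))
    stop("neighbour counts cannot exceed the Z universe size n_z")
  if (any(k_xy < 0) || any(k_xy > pmin(n_x, n_y)))
    stop("k_xy must lie in [0, min(n_x, n_y)]")
  stats::phyper(k_xy - 1, m = n_x, n = n_z - n_x, k = n_y,
                lower.tail = FALSE)
}

#' Bonferroni-corrected significance level
#'
#' The family-wise threshold 0.05 / n for testing `n_edges` predicted edges:
#' a per-edge p-value below it is called statistically significant.
#'
#' @param n_edges number of edges tested (>= 1)
#' @return the corrected alpha
#' @export
bonferroni_alpha <- function(n_edges) {
  if (length(n_edges) != 1 || n_edges < 1) stop("n_edges must be >= 1")
  0.05 / n_edges
}

#' Classify an association as Gold, Silver or Bronze
#'
#' A per-dataset p-value is significant when strictly below `alpha`. The
#' association is Gold when every dataset that has data for the pair is
#' significant, Silver when more than half of them are, and Bronze
#' otherwise. Datasets without data (NA p-values) are excluded from the
#' denominator.
#'
#' @param p_values numeric vector of per-dataset p-values; `NA` marks a
#'   dataset with no data for the pair
#' @param alpha significance level (typically [bonferroni_alpha()])
#' @return `"Gold"`, `"Silver"` or `"Bronze"`
#' @export
classify_association <- function(p_values, alpha) {
  present <- !is.na(p_values)
  if (!any(present)) stop("no dataset has data for this pair")
  sig <- p_values[present] < alpha
  if (all(sig)) "Gold"
  else if (mean(sig) > 0.5) "Silver"
  else "Bronze"
}

#' Annotate filtered predictions with significance and quality classes
#'
#' Assembles one record per surviving entry of the filtered consensus
#' matrix: the consensus score, the known/novel flag, per-dataset
#' common-neighbour counts and hypergeometric p-values, and the
#' Gold/Silver/Bronze class at the Bonferroni level 0.05 / (number of kept
#' edges). A dataset contributes a p-value for a pair only when both x and y
#' have at least one neighbour in that dataset's (clustered) graphs; other
#' datasets are recorded as NA (absent). The Z universe size of each
#' dataset's null is the number of distinct Z items observed in its edges.
#'
#' @param cs_filtered a [filter_similarity()] result
#' @param datasets named list; each element a list with bigraphs `g1` (X-Z)
#'   and `g2` (Y-Z) — the same clustered (and optionally propagated) graphs
#'   that produced the per-dataset similarities
#' @param e3 data frame of known (x, y) associations
#' @return data frame of class `codac_associations` with columns `x`, `y`,
#'   `consensus_score`, `known`, `quality` and one `p_<dataset>` column per
#'   dataset, sorted by descending score then (x, y); attributes `alpha` and
#'   `n_edges` carry the correction context
#' @export
annotate_predictions <- function(cs_filtered, datasets, e3) {
  e3 <- as_pairs(e3)
  ent <- similarity_entries(cs_filtered$sim)
  ids <- names(datasets)
  if (is.null(ids) || any(ids == ""))
    stop("datasets must be a named list")
  if (nrow(ent) == 0) {
    out <- data.frame(x = character(), y = character(),
                      consensus_score = numeric(), known = logical(),
                      quality = character(), stringsAsFactors = FALSE)
    for (id in ids) out[[paste0("p_", id)]] <- numeric()
    class(out) <- c("codac_associations", "data.frame")
    attr(out, "alpha") <- NA_real_
    attr(out, "n_edges") <- 0L
    return(out)
  }
  n_edges <- nrow(ent)
  alpha <- bonferroni_alpha(n_edges)
  pmat <- matrix(NA_real_, nrow = n_edges, ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (id in ids) {
    dg <- datasets[[id]]
    if (!all(c("g1", "g2") %in% names(dg)))
      stop("dataset '", id, "' must carry bigraphs g1 and g2")
    # the dataset's Z universe for the null: items observed in its edges
    z_order <- sort(union(unique(dg$g1$edges$right),
                          unique(dg$g2$edges$right)))
    m1 <- build_biadjacency(dg$g1, z_order)
    m2 <- build_biadjacency(dg$g2, z_order)
    k_mat <- Matrix::tcrossprod(m1, m2)  # common-neighbour counts
    n_x <- Matrix::rowSums(m1)
    n_y <- Matrix::rowSums(m2)
    n_z <- length(z_order)
    i <- match(ent$x, rownames(m1))
    j <- match(ent$y, rownames(m2))
    has <- !is.na(i) & !is.na(j)
    has[has] <- n_x[i[has]] > 0 & n_y[j[has]] > 0
    if (any(has)) {
      k <- k_mat[cbind(i[has], j[has])]
      pmat[has, id] <- hypergeometric_pvalue(n_z, n_x[i[has]], n_y[j[has]], k)
    }
  }
  quality <- vapply(seq_len(n_edges), function(r)
    classify_association(pmat[r, ], alpha), character(1))
  out <- data.frame(x = ent$x, y = ent$y, consensus_score = ent$score,
                    known = edge_keys(ent$x, ent$y) %in%
                      edge_keys(e3$x, e3$y),
                    quality = quality, stringsAsFactors = FALSE)
  for (id in ids) out[[paste0("p_", id)]] <- pmat[, id]
  out <- out[order(-out$consensus_score, out$x, out$y), ]
  rownames(out) <- NULL
  class(out) <- c("codac_associations", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "n_edges") <- n_edges
  out
}

#' Write annotated associations as TSV
#'
#' Columns: `x_id`, optional `x_name` (when an ontology is supplied),
#' `y_id`, `consensus_score` (6 decimals), `quality`, `known`, then one
#' p-value column per dataset (empty when the dataset has no data for the
#' pair).
#'
#' @param assocs an [annotate_predictions()] result
#' @param path output path
#' @param o optional [ontology()] used to fill `x_name`
#' @export
write_associations_tsv <- function(assocs, path, o = NULL) {
  df <- as.data.frame(assocs)
  out <- data.frame(x_id = df$x, stringsAsFactors = FALSE)
  if (!is.null(o)) {
    nm <- o$terms$name[match(df$x, o$terms$id)]
    out$x_name <- ifelse(is.na(nm), "", nm)
  }
  out$y_id <- df$y
  out$consensus_score <- sprintf("%.6f", df$consensus_score)
  out$quality <- df$quality
  out$known <- ifelse(df$known, "known", "novel")
  for (col in grep("^p_", names(df), value = TRUE))
    out[[col]] <- ifelse(is.na(df[[col]]), "",
                         sprintf("%.6g", df[[col]]))
  if ("most_specific" %in% names(df))
    out$most_specific <- ifelse(df$most_specific, "yes", "no")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
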