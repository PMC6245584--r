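#' Row-normalize a biadjacency matrix to unit Euclidean norm
#'
#' Each nonzero row is scaled to unit L2 norm; all-zero rows (items with no
#' neighbours) stay all-zero, so downstream cosine scores involving them are
#' 0 rather than NaN.
#'
#' @param m sparse 0/1 matrix as from [build_biadjacency()]
#' @return sparse real matrix of the same shape
#' @export
row_normalize <- function(m) {
  norms <- sqrt(Matrix::rowSums(m^2))
  scale <- ifelse(norms > 0, 1 / norms, 0)
  out <- Matrix::Diagonal(x = scale) %*% m
  dimnames(out) <- dimnames(m)
  out
}

#' Cosine neighbourhood similarity between two bigraph layers
#'
#' For biadjacency matrices M1 (|X| x |Z|) and M2 (|Y| x |Z|) over an
#' identical Z column layout, computes C = U1 U2' where U1, U2 are the
#' row-normalized matrices. Entry (x, y) equals
#' |N(x) inter N(y)| / sqrt(deg(x) deg(y)), the cosine of the two 0/1
#' neighbourhood vectors. Zeros are not materialized: an entry is stored only
#' when the pair shares at least one common neighbour.
#'
#' @param m1,m2 sparse 0/1 biadjacency matrices with identical column
#'   vocabulary and order (shared Z)
#' @param dataset_id label for the evidence dataset these layers come from
#' @return an object of class `dataset_similarity`: list with `dataset_id`
#'   and `sim`, a sparse |X| x |Y| matrix of scores in \[0, 1\]
#' @export
cosine_similarity <- function(m1, m2, dataset_id = "dataset") {
  if (is.null(colnames(m1)) || is.null(colnames(m2)) ||
      !identical(colnames(m1), colnames(m2)))
    stop("m1 and m2 must share an identical Z column vocabulary and order")
  C <- Matrix::tcrossprod(row_normalize(m1), row_normalize(m2))
  C <- Matrix::drop0(C)
  C@x <- pmin(C@x, 1)  # guard rounding above 1 for identical neighbourhoods
  structure(list(dataset_id = dataset_id,
                 sim = methods::as(C, "CsparseMatrix")),
            class = "dataset_similarity")
}

#' @export
print.dataset_similarity <- function(x, ...) {
  cat(sprintf("dataset_similarity '%s': %d x %d, %d nonzero scores\n",
              x$dataset_id, nrow(x$sim), ncol(x$sim),
              length(x$sim@x)))
  invisible(x)
}

# internal: extract the nonzero entries of a sparse similarity matrix
# as a data frame (x, y, score)
similarity_entries <- function(sim) {
  tr <- Matrix::summary(methods::as(sim, "TsparseMatrix"))
  data.frame(x = rownames(sim)[tr$i], y = colnames(sim)[tr$j],
             score = tr$x, stringsAsFactors = FALSE)
}

#' Weighted-average consensus of per-dataset similarity matrices
#'
#' CS(x, y) = sum_d w_d C^d(x, y) / sum_d w_d over *all* datasets, with
#' C^d(x, y) = 0 whenever dataset d has no score for the pair. The row and
#' column vocabularies of the consensus are the sorted unions across
#' datasets.
#'
#' @param sims list of `dataset_similarity` objects with unique dataset ids
#' @param weights named numeric vector of positive weights covering every
#'   dataset id; defaults to weight 1 for each dataset
#' @return an object of class `consensus_similarity`: list with `sim`
#'   (sparse union-X x union-Y matrix) and `weights`
#' @export
consensus <- function(sims, weights = NULL) {
  if (length(sims) == 0) stop("at least one dataset similarity is required")
  ids <- vapply(sims, function(s) s$dataset_id, character(1))
  if (anyDuplicated(ids)) stop("dataset ids must be unique")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(ids)), ids)
  missing_w <- setdiff(ids, names(weights))
  if (length(missing_w) > 0)
    stop("weights missing for dataset(s): ", paste(missing_w, collapse = ", "))
  weights <- weights[ids]
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all dataset weights must be positive")
  rows <- sort(Reduce(union, lapply(sims, function(s) rownames(s$sim))))
  cols <- sort(Reduce(union, lapply(sims, function(s) colnames(s$sim))))
  acc <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(rows), length(cols)),
                              dimnames = list(rows, cols))
  for (k in seq_along(sims)) {
    tr <- Matrix::summary(methods::as(sims[[k]]$sim, "TsparseMatrix"))
    if (nrow(tr) == 0) next
    part <- Matrix::sparseMatrix(
      i = match(rownames(sims[[k]]$sim)[tr$i], rows),
      j = match(colnames(sims[[k]]$sim)[tr$j], cols),
      x = tr$x * weights[k],
      dims = c(length(rows), length(cols)), dimnames = list(rows, cols))
    acc <- acc + part
  }
  acc <- Matrix::drop0(acc / sum(weights))
  structure(list(sim = methods::as(acc, "CsparseMatrix"),
                 weights = weights),
            class = "consensus_similarity")
}

#' @export
print.consensus_similarity <- function(x, ...) {
  cat(sprintf("consensus_similarity: %d x %d, %d nonzero scores; weights: %s\n",
              nrow(x$sim), ncol(x$sim), length(x$sim@x),
              paste(sprintf("%s=%.1f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Look up similarity scores for specific (x, y) pairs
#'
#' Pairs absent from the matrix (including pairs whose x or y is outside the
#' vocabulary) score 0, matching the convention used throughout calibration.
#'
#' @param s a `dataset_similarity` or `consensus_similarity`
#' @param pairs data frame with columns `x` and `y`
#' @return numeric vector of scores, one per row of `pairs`
#' @export
score_pairs <- function(s, pairs) {
  sim <- if (inherits(s, c("dataset_similarity", "consensus_similarity")))
    s$sim else s
  i <- match(pairs$x, rownames(sim))
  j <- match(pairs$y, colnames(sim))
  out <- numeric(nrow(pairs))
  ok <- !is.na(i) & !is.na(j)
  if (any(ok)) out[ok] <- sim[cbind(i[ok], j[ok])]
  out
}

#' Export a similarity matrix as three-column TSV
#'
#' Writes one line per stored (nonzero) score: `x_id`, `y_id`, `score` with
#' six decimal places, sorted by (x, y) for reproducible output.
#'
#' @param s a `dataset_similarity` or `consensus_similarity`
#' @param path output file path
#' @export
write_similarity_tsv <- function(s, path) {
  sim <- if (inherits(s, c("dataset_similarity", "consensus_similarity")))
    s$sim else s
  df <- similarity_entries(sim)
  df <- df[order(df$x, df$y), ]
  lines <- sprintf("%s\t%s\t%.6f", df$x, df$y, df$score)
  writeLines(lines, path)
  invisible(path)
}
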