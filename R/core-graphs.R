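#' Construct a bipartite graph (bigraph)
#'
#' A bigraph is one layer of the tripartite input: an ordered left vocabulary
#' (role X or Y), an ordered right vocabulary (role Z), and a set of
#' undirected, unweighted edges between them. Duplicate edges are merged.
#'
#' @param edges two-column data frame (or matrix) of character identifiers,
#'   first column left, second column right. May have zero rows.
#' @param left_items,right_items optional explicit vocabularies. When `NULL`
#'   the vocabulary is the lexicographically sorted set of identifiers seen in
#'   `edges`. Explicit vocabularies may include isolated items and fix the
#'   ordering used by downstream matrices.
#' @return an object of class `bigraph` with fields `left_items`,
#'   `right_items` and `edges` (a deduplicated two-column data frame with
#'   columns `left`, `right`).
#' @examples
#' g <- bigraph(data.frame(left = c("x1", "x1"), right = c("z1", "z3")))
#' g$left_items
#' @export
bigraph <- function(edges, left_items = NULL, right_items = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2 && nrow(edges) > 0)
    stop("edges must have two columns (left, right)")
  if (nrow(edges) == 0) {
    edges <- data.frame(left = character(), right = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(left = as.character(edges[[1]]),
                        right = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
  }
  if (anyNA(edges$left) || anyNA(edges$right))
    stop("edge identifiers must not be NA")
  if (is.null(left_items)) {
    left_items <- sort(unique(edges$left))
  } else {
    left_items <- as.character(left_items)
    if (anyDuplicated(left_items))
      stop("left_items contains duplicate identifiers")
    missing <- setdiff(edges$left, left_items)
    if (length(missing) > 0)
      stop("edge left identifiers absent from left_items: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  if (is.null(right_items)) {
    right_items <- sort(unique(edges$right))
  } else {
    right_items <- as.character(right_items)
    if (anyDuplicated(right_items))
      stop("right_items contains duplicate identifiers")
    missing <- setdiff(edges$right, right_items)
    if (length(missing) > 0)
      stop("edge right identifiers absent from right_items: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(left_items = left_items, right_items = right_items,
                 edges = edges),
            class = "bigraph")
}

#' @export
print.bigraph <- function(x, ...) {
  cat(sprintf("bigraph: %d left x %d right items, %d edges\n",
              length(x$left_items), length(x$right_items), nrow(x$edges)))
  invisible(x)
}

#' Per-item degrees of a bigraph side
#'
#' @param g a [bigraph()]
#' @param side `"left"` or `"right"`
#' @return named integer vector over the full vocabulary of that side
#'   (isolated items have degree 0)
#' @export
bigraph_degrees <- function(g, side = c("left", "right")) {
  side <- match.arg(side)
  vocab <- if (side == "left") g$left_items else g$right_items
  d <- table(factor(g$edges[[side]], levels = vocab))
  stats::setNames(as.integer(d), vocab)
}

# internal: encode edge pairs as single keys for fast set membership
edge_keys <- function(left, right) paste(left, right, sep = "\r")

#' Build the biadjacency matrix of a bigraph
#'
#' Rows follow the bigraph's left vocabulary; columns follow `col_order`,
#' which must cover every right identifier used by an edge. Sharing one
#' `col_order` between the X-Z and Y-Z bigraphs of a dataset guarantees that
#' their matrices have an identical Z column layout, which cosine scoring
#' requires.
#'
#' @param g a [bigraph()]
#' @param col_order ordered character vector of column identifiers; defaults
#'   to `g$right_items`. Items absent from `g` give all-zero columns.
#' @return a sparse 0/1 `dgCMatrix` with dimnames
#' @export
build_biadjacency <- function(g, col_order = NULL) {
  stopifnot(inherits(g, "bigraph"))
  if (is.null(col_order)) col_order <- g$right_items
  col_order <- as.character(col_order)
  if (anyDuplicated(col_order)) stop("col_order contains duplicates")
  j <- match(g$edges$right, col_order)
  if (anyNA(j)) {
    bad <- unique(g$edges$right[is.na(j)])
    stop("edge right identifier(s) missing from col_order: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  i <- match(g$edges$left, g$left_items)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(g$left_items), length(col_order)),
                       dimnames = list(g$left_items, col_order))
}

#' Read a bigraph back from a biadjacency matrix
#'
#' Inverse of [build_biadjacency()]: nonzero entries become edges.
#'
#' @param m a sparse matrix with dimnames as produced by [build_biadjacency()]
#' @return a [bigraph()] whose right vocabulary is the full column set of `m`
#' @export
biadjacency_to_bigraph <- function(m) {
  tr <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  bigraph(data.frame(left = rownames(m)[tr$i], right = colnames(m)[tr$j],
                     stringsAsFactors = FALSE),
          left_items = rownames(m), right_items = colnames(m))
}

#' Identity cluster map
#'
#' Synthesizes the trivial map in which every common-neighbour (Z) item is
#' its own singleton cluster, used when no redundancy clustering is supplied.
#'
#' @param z_items character vector of Z identifiers
#' @return named character vector z_id -> cluster id (here, itself)
#' @export
identity_cluster_map <- function(z_items) {
  z_items <- unique(as.character(z_items))
  stats::setNames(z_items, z_items)
}

#' Collapse redundant common-neighbour items into clusters
#'
#' Replaces every Z item in both bigraphs by its cluster identifier (CID) and
#' merges the duplicate edges this creates. Redundant Z items (e.g. protein
#' entries with identical sequences) otherwise bias neighbourhood similarity;
#' collapsing them can also connect an x and a y that were each seen with a
#' different copy of the same underlying item.
#'
#' @param g1,g2 bigraphs sharing role Z on their right side (X-Z and Y-Z)
#' @param cm named character vector mapping every Z identifier of both graphs
#'   to a CID; `NULL` synthesizes the identity map (no clustering)
#' @return list with elements `g1` and `g2`: the reduced bigraphs whose right
#'   vocabulary is the sorted set of CIDs appearing in either graph
#' @export
cluster_common_items <- function(g1, g2, cm = NULL) {
  stopifnot(inherits(g1, "bigraph"), inherits(g2, "bigraph"))
  z_all <- union(g1$right_items, g2$right_items)
  if (is.null(cm)) cm <- identity_cluster_map(z_all)
  if (is.null(names(cm))) stop("cluster map must be a named vector (z -> CID)")
  uncovered <- setdiff(z_all, names(cm))
  if (length(uncovered) > 0)
    stop("cluster map does not cover Z item(s): ",
         paste(utils::head(uncovered, 5), collapse = ", "),
         " (clustering must be total)")
  cids <- sort(unique(unname(cm[z_all])))
  remap <- function(g) {
    e <- g$edges
    e$right <- unname(cm[e$right])
    bigraph(unique(e), left_items = g$left_items, right_items = cids)
  }
  list(g1 = remap(g1), g2 = remap(g2))
}

#' Read a two-column edge list from TSV
#'
#' Lines starting with `#` are ignored; fields are tab-separated and
#' whitespace-trimmed. UTF-8 is assumed.
#'
#' @param path file path
#' @return two-column character data frame (`left`, `right`)
#' @export
read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", blank.lines.skip = TRUE,
                          quote = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("edge list must have two tab-separated columns: ", path)
  data.frame(left = trimws(df[[1]]), right = trimws(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Read a cluster map (z_id -> CID) from TSV
#'
#' @param path file path to a two-column TSV (`z_id`, `cid`); `#` comments
#'   ignored
#' @return named character vector mapping z_id to CID
#' @export
read_cluster_map_tsv <- function(path) {
  df <- read_edge_tsv(path)
  if (anyDuplicated(df$left))
    stop("cluster map assigns multiple CIDs to the same Z item")
  stats::setNames(df$right, df$left)
}

#' Write an edge list as two-column TSV
#' @param edges two-column data frame
#' @param path output file path
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(edges[, 1:2], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
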