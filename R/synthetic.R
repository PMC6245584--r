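# Synthetic tripartite fixtures: planted X-Y associations expressed as
# correlated neighbourhoods in Z, plus background noise edges, an artificial
# rooted-DAG ontology over X, and a redundancy cluster map over Z.

#' Specification of a synthetic tripartite study
#'
#' The defaults define the reference desk-scale conditions used throughout
#' the package's tests: 50 x 50 vocabularies indirectly connected through
#' 500 common-neighbour items, 60 planted associations each owning a
#' dedicated block of Z items that co-link to both endpoints with
#' probability `signal`, sparse independent noise edges, and three evidence
#' datasets of equal quality. Half of the planted pairs are declared as the
#' known associations available for calibration; the other half are held out
#' to measure recovery.
#'
#' @param n_x,n_y,n_z vocabulary sizes for X, Y and Z
#' @param n_planted number of true X-Y associations to plant
#' @param signal probability that a z in a planted pair's block links to
#'   each endpoint (per dataset, scaled by `dataset_quality`)
#' @param noise probability of a spurious independent X-Z or Y-Z edge
#' @param n_datasets number of evidence datasets
#' @param dataset_quality per-dataset multiplier on `signal`
#' @param ontology_depth,ontology_branching shape of the artificial rDAG of
#'   internal terms above the X leaves
#' @param cluster_redundancy probability that a Z item has a redundant
#'   duplicate (an independently re-observed copy mapped to the same cluster)
#' @param known_fraction fraction of planted pairs declared as known
#'   associations (E3) for calibration; the rest are held out
#' @param block_overlap if `TRUE`, consecutive planted pairs share half of
#'   their Z blocks, emulating multi-function items; default disjoint blocks
#' @param seed integer master seed
#' @return a validated list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_x = 50, n_y = 50, n_z = 500, n_planted = 60,
                           signal = 0.8, noise = 0.01, n_datasets = 3,
                           dataset_quality = rep(1, n_datasets),
                           ontology_depth = 3, ontology_branching = 3,
                           cluster_redundancy = 0.1, known_fraction = 0.5,
                           block_overlap = FALSE, seed = 1) {
  spec <- list(n_x = n_x, n_y = n_y, n_z = n_z, n_planted = n_planted,
               signal = signal, noise = noise, n_datasets = n_datasets,
               dataset_quality = dataset_quality,
               ontology_depth = ontology_depth,
               ontology_branching = ontology_branching,
               cluster_redundancy = cluster_redundancy,
               known_fraction = known_fraction,
               block_overlap = isTRUE(block_overlap), seed = seed)
  probs <- c(spec$signal, spec$noise, spec$cluster_redundancy,
             spec$known_fraction, spec$signal * spec$dataset_quality)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (spec$n_planted > spec$n_x * spec$n_y)
    stop("cannot plant more associations than |X| x |Y|")
  if (length(spec$dataset_quality) != spec$n_datasets)
    stop("dataset_quality must have one entry per dataset")
  if (spec$signal <= spec$noise)
    warning("signal <= noise: planted associations are not recoverable")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic tripartite fixture
#'
#' Plants `n_planted` (x, y) associations, assigns each a block of Z items,
#' and, independently for each dataset, links every block item to both
#' endpoints with probability `signal * dataset_quality[d]`; every possible
#' X-Z and Y-Z edge is additionally present with probability `noise`. A
#' fraction of Z items have duplicate copies whose edges are re-drawn from
#' the same probabilities — the cluster map groups each duplicate with its
#' original, so redundancy clustering can recover co-links split across
#' copies. An artificial rDAG places every X identifier as a leaf under
#' `ontology_depth` layers of internal terms. Fully reproducible given the
#' spec seed.
#'
#' @param spec a [synthetic_spec()]
#' @return list of class `codac_fixture` with elements `datasets` (named
#'   list of `list(g1, g2)` bigraph pairs), `e3_true` (all planted pairs),
#'   `e3_given` (the declared known subset), `e3_heldout`, `ontology`,
#'   `cluster_map` and `spec`
#' @export
generate_tripartite <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    x_ids <- sprintf("X%03d", seq_len(spec$n_x))
    y_ids <- sprintf("Y%03d", seq_len(spec$n_y))
    z_ids <- sprintf("Z%04d", seq_len(spec$n_z))

    # planted pairs form a matching as far as the vocabularies allow, so
    # each planted association owns its endpoints (and, with noise = 0, its
    # block gives cosine exactly 1); endpoints are reused only when
    # n_planted exceeds a side's size
    draw_side <- function(n_items, n_needed) {
      base <- sample.int(n_items, min(n_items, n_needed))
      if (n_needed > n_items)
        base <- c(base, sample.int(n_items, n_needed - n_items,
                                   replace = TRUE))
      base
    }
    repeat {
      xi <- draw_side(spec$n_x, spec$n_planted)
      yi <- draw_side(spec$n_y, spec$n_planted)
      if (!anyDuplicated(paste(xi, yi))) break
    }
    planted <- data.frame(x = x_ids[xi], y = y_ids[yi],
                          stringsAsFactors = FALSE)

    # dedicated z block per planted pair; with block_overlap, consecutive
    # pairs share the trailing half of the previous block
    block_size <- max(1L, spec$n_z %/% spec$n_planted)
    block_of <- lapply(seq_len(spec$n_planted), function(k) {
      own <- ((k - 1) * block_size + 1):min(k * block_size, spec$n_z)
      if (spec$block_overlap && k > 1) {
        prev <- ((k - 2) * block_size + 1):min((k - 1) * block_size, spec$n_z)
        own <- union(utils::tail(prev, length(prev) %/% 2), own)
      }
      own
    })

    # redundant duplicates of z items
    dup_mask <- stats::runif(spec$n_z) < spec$cluster_redundancy
    dup_ids <- if (any(dup_mask)) paste0(z_ids[dup_mask], "dup")
      else character(0)
    z_all <- c(z_ids, dup_ids)
    # block membership per z column of the extended universe
    src <- c(seq_len(spec$n_z), which(dup_mask))
    cluster_map <- stats::setNames(c(z_ids, z_ids[dup_mask]), z_all)

    datasets <- list()
    for (d in seq_len(spec$n_datasets)) {
      p_sig <- spec$signal * spec$dataset_quality[d]
      ex <- matrix(stats::runif(spec$n_x * length(z_all)) < spec$noise,
                   nrow = spec$n_x)
      ey <- matrix(stats::runif(spec$n_y * length(z_all)) < spec$noise,
                   nrow = spec$n_y)
      for (k in seq_len(spec$n_planted)) {
        cols <- which(src %in% block_of[[k]])
        xi <- match(planted$x[k], x_ids)
        yi <- match(planted$y[k], y_ids)
        ex[xi, cols] <- ex[xi, cols] | (stats::runif(length(cols)) < p_sig)
        ey[yi, cols] <- ey[yi, cols] | (stats::runif(length(cols)) < p_sig)
      }
      wx <- which(ex, arr.ind = TRUE)
      wy <- which(ey, arr.ind = TRUE)
      g1 <- bigraph(data.frame(left = x_ids[wx[, 1]], right = z_all[wx[, 2]],
                               stringsAsFactors = FALSE),
                    left_items = x_ids, right_items = z_all)
      g2 <- bigraph(data.frame(left = y_ids[wy[, 1]], right = z_all[wy[, 2]],
                               stringsAsFactors = FALSE),
                    left_items = y_ids, right_items = z_all)
      datasets[[sprintf("D%d", d)]] <- list(g1 = g1, g2 = g2)
    }

    n_known <- floor(spec$known_fraction * spec$n_planted)
    known_rows <- sample.int(spec$n_planted, n_known)
    e3_given <- planted[sort(known_rows), , drop = FALSE]
    e3_heldout <- planted[setdiff(seq_len(spec$n_planted), known_rows), ,
                          drop = FALSE]
    rownames(e3_given) <- rownames(e3_heldout) <- NULL

    onto <- synthetic_ontology(x_ids, spec$ontology_depth,
                               spec$ontology_branching)

    structure(list(datasets = datasets, e3_true = planted,
                   e3_given = e3_given, e3_heldout = e3_heldout,
                   ontology = onto, cluster_map = cluster_map, spec = spec),
              class = "codac_fixture")
  })
}

# internal: rDAG with a single root, `depth` layers of internal terms
# (branching^level per layer), and the x identifiers as leaves, each
# attached to 1-2 parents in the deepest internal layer
synthetic_ontology <- function(x_ids, depth, branching) {
  layers <- list("SYN:ROOT")
  for (lv in seq_len(max(depth - 1, 0)))
    layers[[lv + 1]] <- sprintf("SYN:L%d.%02d", lv,
                                seq_len(min(branching^lv, 64)))
  internal <- unlist(layers)
  parents <- list()
  for (lv in seq_along(layers)[-1]) {
    for (t in layers[[lv]])
      parents[[t]] <- sample(layers[[lv - 1]], 1)
  }
  deepest <- layers[[length(layers)]]
  for (x in x_ids) {
    k <- 1 + (stats::runif(1) < 0.3)  # occasional diamond: two parents
    parents[[x]] <- sample(deepest, min(k, length(deepest)))
  }
  ontology(data.frame(id = c(internal, x_ids),
                      name = paste("synthetic term", c(internal, x_ids)),
                      namespace = "synthetic",
                      stringsAsFactors = FALSE),
           parents)
}

#' Write a synthetic fixture to disk
#'
#' Emits the exact plain-text formats the loaders consume: per-dataset X-Z
#' and Y-Z edge TSVs, the known-association TSV (`e3_given.tsv`), the full
#' truth TSV for evaluation (`e3_true.tsv`, with a `known`/`heldout` third
#' column), the cluster map TSV, and the ontology as OBO.
#'
#' @param fix a [generate_tripartite()] fixture
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(fix, dir) {
  stopifnot(inherits(fix, "codac_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(fix$datasets)) {
    write_edge_tsv(fix$datasets[[id]]$g1$edges,
                   file.path(dir, paste0(id, "_xz.tsv")))
    write_edge_tsv(fix$datasets[[id]]$g2$edges,
                   file.path(dir, paste0(id, "_yz.tsv")))
  }
  write_edge_tsv(fix$e3_given, file.path(dir, "e3_given.tsv"))
  truth <- fix$e3_true
  truth$status <- ifelse(edge_keys(truth$x, truth$y) %in%
                           edge_keys(fix$e3_given$x, fix$e3_given$y),
                         "known", "heldout")
  utils::write.table(truth, file.path(dir, "e3_true.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_edge_tsv(data.frame(left = names(fix$cluster_map),
                            right = unname(fix$cluster_map)),
                 file.path(dir, "cluster_map.tsv"))
  write_obo(fix$ontology, file.path(dir, "ontology.obo"))
  invisible(dir)
}
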