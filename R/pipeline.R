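# End-to-end orchestration: cluster -> [propagate] -> per-dataset cosine ->
# weight optimization -> consensus -> shuffled gold standard -> threshold ->
# filter -> significance -> quality classes -> [most-specific filter].

#' Assemble and validate a run configuration
#'
#' Datasets may be given in-memory (`list(g1 =, g2 =)` bigraphs) or as file
#' paths (`list(xz =, yz =)` edge TSVs, optional `cluster_map`). A shared
#' `cluster_map` applies to every dataset without its own; with neither,
#' singleton clusters are synthesized (no clustering).
#'
#' @param datasets named list of dataset declarations (unique ids)
#' @param known known X-Y associations: data frame of pairs or a TSV path
#' @param cluster_map optional shared map: named vector or TSV path
#' @param ontology optional [ontology()] or OBO path
#' @param namespace optional namespace restriction applied when reading OBO
#' @param propagate propagate X-Z annotations up the ontology before
#'   similarity scoring (default off)
#' @param most_specific flag predictions that are most-specific per y
#'   (requires an ontology; default on when one is supplied)
#' @param weight_strategy `"coordinate_ascent"` or `"exhaustive"`
#' @param seed master integer seed; all stage seeds derive from it by fixed
#'   offsets
#' @return validated config list of class `codac_config`
#' @export
codac_config <- function(datasets, known, cluster_map = NULL,
                         ontology = NULL, namespace = NULL,
                         propagate = FALSE, most_specific = NULL,
                         weight_strategy = "coordinate_ascent", seed = 1) {
  if (length(datasets) == 0 || is.null(names(datasets)) ||
      anyDuplicated(names(datasets)))
    abort_with_class("datasets must be a named list with unique ids",
                     "codac_validation")
  for (id in names(datasets)) {
    dd <- datasets[[id]]
    if (all(c("g1", "g2") %in% names(dd))) next
    if (!all(c("xz", "yz") %in% names(dd)))
      abort_with_class(sprintf(
        "dataset '%s' must supply either g1/g2 bigraphs or xz/yz paths", id),
        "codac_validation")
    for (p in c(dd$xz, dd$yz, dd$cluster_map))
      if (!file.exists(p))
        abort_with_class(sprintf("dataset '%s': file not found: %s", id, p),
                         "codac_validation")
  }
  is_path <- function(p) is.character(p) && length(p) == 1 &&
    is.null(names(p))
  if (is_path(known) && !file.exists(known))
    abort_with_class(paste("known-association file not found:", known),
                     "codac_validation")
  if (is_path(cluster_map) && !file.exists(cluster_map))
    abort_with_class(paste("cluster map file not found:", cluster_map),
                     "codac_validation")
  if (is_path(ontology) && !file.exists(ontology))
    abort_with_class(paste("ontology file not found:", ontology),
                     "codac_validation")
  if (is.null(most_specific)) most_specific <- !is.null(ontology)
  structure(list(datasets = datasets, known = known,
                 cluster_map = cluster_map, ontology = ontology,
                 namespace = namespace, propagate = isTRUE(propagate),
                 most_specific = isTRUE(most_specific),
                 weight_strategy = weight_strategy,
                 seed = as.integer(seed)),
            class = "codac_config")
}

# internal: materialize config inputs (read files where paths were given)
resolve_config <- function(config) {
  is_path <- function(p) is.character(p) && length(p) == 1 &&
    is.null(names(p))
  shared_cm <- config$cluster_map
  if (is_path(shared_cm)) shared_cm <- read_cluster_map_tsv(shared_cm)
  datasets <- list()
  for (id in names(config$datasets)) {
    dd <- config$datasets[[id]]
    if (all(c("g1", "g2") %in% names(dd))) {
      g1 <- dd$g1; g2 <- dd$g2
    } else {
      e1 <- read_edge_tsv(dd$xz); e2 <- read_edge_tsv(dd$yz)
      z <- sort(union(e1$right, e2$right))
      g1 <- bigraph(e1, right_items = z)
      g2 <- bigraph(e2, right_items = z)
    }
    cm <- if (!is.null(dd$cluster_map)) {
      if (is_path(dd$cluster_map)) read_cluster_map_tsv(dd$cluster_map)
      else dd$cluster_map
    } else shared_cm
    datasets[[id]] <- list(g1 = g1, g2 = g2, cluster_map = cm)
  }
  known <- config$known
  if (is.character(known)) known <- read_edge_tsv(known)
  known <- as_pairs(known)
  onto <- config$ontology
  if (is.character(onto)) onto <- read_obo(onto, namespace = config$namespace)
  list(datasets = datasets, known = known, ontology = onto)
}

#' Run the full association-prediction pipeline
#'
#' Executes, in order: redundancy clustering of each dataset's Z items,
#' optional ontology propagation of the X-Z layer, per-dataset cosine
#' similarity, AUC-optimized dataset weights, the weighted consensus,
#' degree-preserving shuffling of every evidence layer to build the gold
#' standard, F-measure threshold selection, score filtering, hypergeometric
#' significance with Bonferroni correction, Gold/Silver/Bronze classes, and
#' (with an ontology) most-specific flagging. Re-running with the same
#' config and seed reproduces identical outputs.
#'
#' @param config a [codac_config()]
#' @param out_dir optional output directory; when given, writes
#'   `associations.tsv`, `gold_standard.tsv`, `manifest.json` and `log.txt`
#' @return list of class `codac_run`: `similarities`, `weight_search`,
#'   `consensus`, `gold_standard`, `calibration`, `filtered`, `associations`
#'   and `manifest`
#' @export
run_predict <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "codac_config"))
  log_lines <- character()
  note <- function(...) {
    line <- sprintf("[%s] %s", "codac", sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "codac_shuffle_failure") ||
          inherits(e, "codac_degenerate_calibration") ||
          inherits(e, "codac_validation")) stop(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- config$seed
  inputs <- stage("load", resolve_config(config))

  clustered <- list()
  for (id in names(inputs$datasets)) {
    dd <- inputs$datasets[[id]]
    clustered[[id]] <- stage("cluster",
                             cluster_common_items(dd$g1, dd$g2,
                                                  dd$cluster_map))
    if (config$propagate && !is.null(inputs$ontology))
      clustered[[id]]$g1 <- stage("propagate",
                                  propagate_ontology(clustered[[id]]$g1,
                                                     inputs$ontology))
    note("dataset %s: %d X-Z and %d Y-Z edges after clustering", id,
         nrow(clustered[[id]]$g1$edges), nrow(clustered[[id]]$g2$edges))
  }

  sims <- list()
  for (id in names(clustered)) {
    cg <- clustered[[id]]
    z <- sort(union(cg$g1$right_items, cg$g2$right_items))
    sims[[id]] <- stage("cosine", cosine_similarity(
      build_biadjacency(cg$g1, z), build_biadjacency(cg$g2, z),
      dataset_id = id))
  }

  ws <- stage("weights", optimize_weights(sims, inputs$known,
                                          strategy = config$weight_strategy))
  note("weights: %s (AUC %.4f)",
       paste(sprintf("%s=%.1f", names(ws$weights), ws$weights),
             collapse = ", "), ws$auc)
  cs <- stage("consensus", consensus(sims, ws$weights))

  shuffled_sims <- list()
  for (k in seq_along(clustered)) {
    id <- names(clustered)[k]
    cg <- clustered[[id]]
    g1s <- shuffle_bigraph(cg$g1, seed = seed + 1000L + k)
    g2s <- shuffle_bigraph(cg$g2, seed = seed + 1500L + k)
    z <- sort(union(g1s$right_items, g2s$right_items))
    shuffled_sims[[id]] <- stage("shuffle-cosine", cosine_similarity(
      build_biadjacency(g1s, z), build_biadjacency(g2s, z), dataset_id = id))
  }
  cs_shuffled <- stage("shuffle-consensus",
                       consensus(shuffled_sims, ws$weights))

  gs <- stage("gold-standard",
              build_gold_standard(inputs$known, cs_shuffled,
                                  seed = seed + 2000L))
  gs <- stage("split", split_gold_standard(gs, seed = seed + 3000L))
  cal <- stage("threshold", select_threshold(cs, gs))
  note("threshold %.3f (F1 train %.3f, test %.3f)",
       cal$threshold, cal$f_train, cal$f_test)

  filtered <- stage("filter", filter_similarity(cs, cal$threshold,
                                                inputs$known))
  assocs <- stage("significance",
                  annotate_predictions(filtered, clustered, inputs$known))
  note("%d kept edges (alpha %.3g): %d Gold, %d Silver, %d Bronze",
       nrow(assocs), attr(assocs, "alpha"),
       sum(assocs$quality == "Gold"), sum(assocs$quality == "Silver"),
       sum(assocs$quality == "Bronze"))

  if (config$most_specific && !is.null(inputs$ontology)) {
    ms <- stage("most-specific",
                most_specific_filter(assocs[, c("x", "y")], inputs$ontology))
    assocs$most_specific <- edge_keys(assocs$x, assocs$y) %in%
      edge_keys(ms$x, ms$y)
  }

  manifest <- list(
    seed = seed,
    datasets = names(clustered),
    weight_strategy = config$weight_strategy,
    weights = as.list(ws$weights),
    auc = ws$auc,
    threshold = cal$threshold,
    f_train = cal$f_train,
    f_test = cal$f_test,
    precision = cal$precision,
    recall = cal$recall,
    n_positives = sum(gs$label == "P"),
    n_negatives = sum(gs$label == "N"),
    n_kept_edges = attr(assocs, "n_edges"),
    alpha = attr(assocs, "alpha"),
    n_known = sum(assocs$known),
    n_novel = sum(!assocs$known),
    class_counts = as.list(table(factor(assocs$quality,
                                        c("Gold", "Silver", "Bronze")))),
    propagate = config$propagate,
    most_specific = config$most_specific)

  run <- structure(list(similarities = sims, weight_search = ws,
                        consensus = cs, gold_standard = gs,
                        calibration = cal, filtered = filtered,
                        associations = assocs, manifest = manifest,
                        log = log_lines),
                   class = "codac_run")
  if (!is.null(out_dir)) write_run(run, out_dir,
                                   ontology = inputs$ontology)
  run
}

#' Write pipeline outputs to a directory
#'
#' @param run a [run_predict()] result
#' @param out_dir output directory (created if needed); partially written
#'   outputs are removed on failure
#' @param ontology optional ontology for term names in the association table
#' @return `out_dir`, invisibly
#' @export
write_run <- function(run, out_dir, ontology = NULL) {
  stopifnot(inherits(run, "codac_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("associations.tsv", "gold_standard.tsv",
                                "manifest.json", "log.txt"))
  tryCatch({
    write_associations_tsv(run$associations, paths[1], o = ontology)
    write_gold_standard_tsv(run$gold_standard, paths[2])
    jsonlite::write_json(run$manifest, paths[3], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(run$log, paths[4])
  }, error = function(e) {
    unlink(paths)
    stop(e)
  })
  invisible(out_dir)
}

#' @export
print.codac_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "codac_run: %d datasets, AUC %.4f, threshold %.3f, %d kept edges (%d novel)\n",
    length(m$datasets), m$auc, m$threshold, m$n_kept_edges, m$n_novel))
  invisible(x)
}

#' Generate and write a synthetic fixture (simulation entry point)
#'
#' Thin wrapper over [synthetic_spec()] + [generate_tripartite()] +
#' [write_fixture()], for use from the command line or scripts.
#'
#' @param spec a [synthetic_spec()], or a YAML file path whose fields are
#'   `synthetic_spec()` arguments, or `NULL` for the defaults
#' @param out_dir fixture output directory
#' @param seed optional seed overriding the spec's
#' @return the generated fixture, invisibly
#' @export
run_simulate <- function(spec = NULL, out_dir, seed = NULL) {
  if (is.null(spec)) spec <- synthetic_spec()
  if (is.character(spec)) {
    args <- yaml::read_yaml(spec)
    spec <- do.call(synthetic_spec, args)
  }
  if (!is.null(seed)) {
    spec$seed <- as.integer(seed)
  }
  fix <- generate_tripartite(spec)
  write_fixture(fix, out_dir)
  invisible(fix)
}

#' Read a YAML run configuration for the command-line interface
#'
#' Expected fields: `datasets` (list of `id`, `xz`, `yz`, optional
#' `cluster_map`), `known`, optional `cluster_map`, `ontology`, `namespace`,
#' `propagate`, `most_specific`, `weight_strategy`, `seed`. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path
#' @return a [codac_config()]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)
  if (is.null(y$datasets))
    abort_with_class("config must declare datasets", "codac_validation")
  datasets <- list()
  for (dd in y$datasets) {
    if (is.null(dd$id))
      abort_with_class("each dataset needs an id", "codac_validation")
    datasets[[dd$id]] <- list(xz = resolve(dd$xz), yz = resolve(dd$yz))
    if (!is.null(dd$cluster_map))
      datasets[[dd$id]]$cluster_map <- resolve(dd$cluster_map)
  }
  codac_config(datasets = datasets, known = resolve(y$known),
               cluster_map = resolve(y$cluster_map),
               ontology = resolve(y$ontology), namespace = y$namespace,
               propagate = isTRUE(y$propagate),
               most_specific = y$most_specific,
               weight_strategy = if (is.null(y$weight_strategy))
                 "coordinate_ascent" else y$weight_strategy,
               seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Evaluate recovery of held-out planted associations
#'
#' Compares the novel (not-known) predictions of a run against a truth set
#' of held-out pairs, e.g. the planted associations a synthetic fixture did
#' not declare as known. By default only statistically supported
#' predictions count as recovered: Gold and Silver records, i.e. pairs
#' whose hypergeometric p-value clears the Bonferroni level in more than
#' half of the data sources. Bronze records are score-only candidates
#' without per-source statistical support and are excluded unless requested.
#'
#' @param assocs a [annotate_predictions()] result (or `codac_run$associations`)
#' @param heldout data frame of true held-out (x, y) pairs
#' @param classes quality classes counted as recovered predictions
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#' @export
evaluate_recovery <- function(assocs, heldout,
                              classes = c("Gold", "Silver")) {
  heldout <- as_pairs(heldout)
  pred <- assocs[!assocs$known & assocs$quality %in% classes,
                 c("x", "y"), drop = FALSE]
  pk <- edge_keys(pred$x, pred$y)
  hk <- edge_keys(heldout$x, heldout$y)
  tp <- sum(pk %in% hk)
  fp <- length(pk) - tp
  fn <- length(hk) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}
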