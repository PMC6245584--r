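# Rooted-DAG ontology support for the X vocabulary: ancestor queries,
# annotation propagation up the is_a hierarchy, and reduction of an
# association set to its most-specific terms.

#' Construct an ontology over term identifiers
#'
#' An ontology here is a rooted directed acyclic graph (rDAG) of terms with
#' `is_a` parent links, as in the Gene Ontology. Loading fails if the parent
#' relation has a cycle or references an unknown term.
#'
#' @param terms data frame with columns `id`, `name`, `namespace` (the
#'   latter two may be missing and default to the id / `""`)
#' @param parents named list mapping a term id to a character vector of its
#'   direct `is_a` parents; terms without an entry have no parents (roots)
#' @return object of class `ontology` with fields `terms` and `parents`
#' @export
ontology <- function(terms, parents = list()) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (!"id" %in% names(terms)) names(terms)[1] <- "id"
  terms$id <- as.character(terms$id)
  if (anyDuplicated(terms$id)) stop("duplicate term identifiers")
  if (is.null(terms$name)) terms$name <- terms$id
  if (is.null(terms$namespace)) terms$namespace <- ""
  parents <- lapply(parents, as.character)
  unknown_child <- setdiff(names(parents), terms$id)
  if (length(unknown_child) > 0)
    stop("parent links for unknown term(s): ",
         paste(utils::head(unknown_child, 5), collapse = ", "))
  unknown_parent <- setdiff(unique(unlist(parents)), terms$id)
  if (length(unknown_parent) > 0)
    stop("unknown parent term(s): ",
         paste(utils::head(unknown_parent, 5), collapse = ", "))
  o <- structure(list(terms = terms[, c("id", "name", "namespace")],
                      parents = parents),
                 class = "ontology")
  assert_acyclic(o)
  o
}

# internal: Kahn's algorithm; stops if the is_a relation has a cycle
assert_acyclic <- function(o) {
  ids <- o$terms$id
  np <- stats::setNames(integer(length(ids)), ids)
  children <- list()
  for (child in names(o$parents)) {
    ps <- o$parents[[child]]
    np[child] <- length(ps)
    for (p in ps) children[[p]] <- c(children[[p]], child)
  }
  queue <- ids[np == 0]
  seen <- 0L
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (c in children[[t]]) {
      np[c] <- np[c] - 1L
      if (np[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(ids))
    stop("ontology is_a relation contains a cycle (not an rDAG)")
  invisible(o)
}

#' @export
print.ontology <- function(x, ...) {
  n_root <- sum(!(x$terms$id %in% names(x$parents)) |
                  vapply(x$terms$id, function(t)
                    length(x$parents[[t]]) == 0, logical(1)))
  cat(sprintf("ontology: %d terms (%d roots), namespaces: %s\n",
              nrow(x$terms), n_root,
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' All ancestors of a term
#'
#' Transitive closure of the `is_a` parent relation, excluding the term
#' itself.
#'
#' @param o an [ontology()]
#' @param term a term identifier present in `o`
#' @return character vector of ancestor identifiers (possibly empty)
#' @export
ancestors <- function(o, term) {
  stopifnot(inherits(o, "ontology"))
  if (!term %in% o$terms$id) stop("unknown term: ", term)
  acc <- character()
  frontier <- o$parents[[term]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, acc)
    acc <- c(acc, frontier)
    frontier <- unique(unlist(o$parents[frontier], use.names = FALSE))
  }
  sort(acc)
}

# internal: ancestor closure for every term, computed once in topological
# order (parents before children)
ancestor_closure <- function(o) {
  ids <- o$terms$id
  clo <- stats::setNames(vector("list", length(ids)), ids)
  remaining <- ids
  done <- character()
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(t)
      all(o$parents[[t]] %in% done), logical(1))]
    for (t in ready) {
      ps <- o$parents[[t]]
      clo[[t]] <- sort(unique(c(ps, unlist(clo[ps], use.names = FALSE))))
    }
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  clo
}

#' Propagate annotations up the ontology
#'
#' For every edge (x, z) of an X-Z bigraph whose left items are ontology
#' terms, adds edges (a, z) for every ancestor a of x that is already present
#' in the graph's left vocabulary. No new vocabulary items are introduced:
#' ancestors outside the graph gain no edges. The operation is idempotent.
#'
#' @param g a [bigraph()] with term identifiers on the left
#' @param o an [ontology()]
#' @param on_missing what to do with left items unknown to the ontology:
#'   `"skip"` (default; they keep their edges and propagate nothing, with a
#'   warning reporting the count) or `"error"`
#' @return the ancestor-propagated [bigraph()]
#' @export
propagate_ontology <- function(g, o, on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(g, "bigraph"), inherits(o, "ontology"))
  unknown <- setdiff(g$left_items, o$terms$id)
  if (length(unknown) > 0) {
    if (on_missing == "error")
      stop("left item(s) missing from ontology: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    warning(length(unknown), " left item(s) unknown to the ontology; ",
            "their edges are kept but not propagated")
  }
  clo <- ancestor_closure(o)
  extra <- lapply(unique(g$edges$left), function(x) {
    if (!x %in% names(clo)) return(NULL)
    anc <- intersect(clo[[x]], g$left_items)
    if (length(anc) == 0) return(NULL)
    zs <- g$edges$right[g$edges$left == x]
    data.frame(left = rep(anc, each = length(zs)),
               right = rep(zs, times = length(anc)),
               stringsAsFactors = FALSE)
  })
  all_edges <- unique(rbind(g$edges, do.call(rbind, extra)))
  bigraph(all_edges, left_items = g$left_items, right_items = g$right_items)
}

#' Reduce associations to their most-specific terms
#'
#' For each y, keeps only associations whose term has no descendant term also
#' associated with the same y: the per-y antichain of most-specific terms,
#' the unit in which association totals are usually counted.
#'
#' @param assocs data frame of (x, y) pairs (columns `x`, `y` or the first
#'   two columns)
#' @param o an [ontology()]
#' @param on_missing as in [propagate_ontology()]; unknown terms are never
#'   removed
#' @return the filtered pair data frame
#' @export
most_specific_filter <- function(assocs, o, on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  assocs <- as_pairs(assocs)
  unknown <- setdiff(unique(assocs$x), o$terms$id)
  if (length(unknown) > 0) {
    if (on_missing == "error")
      stop("term(s) missing from ontology: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    warning(length(unknown), " term(s) unknown to the ontology; ",
            "kept without specificity check")
  }
  clo <- ancestor_closure(o)
  keep <- rep(TRUE, nrow(assocs))
  for (yy in unique(assocs$y)) {
    rows <- which(assocs$y == yy)
    xs <- assocs$x[rows]
    anc_here <- unique(unlist(clo[intersect(xs, names(clo))],
                              use.names = FALSE))
    keep[rows[xs %in% anc_here]] <- FALSE
  }
  assocs[keep, , drop = FALSE]
}

#' Read an ontology from an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas for the tags `id`, `name`, `namespace`, `is_a`
#' and `is_obsolete`; obsolete terms are dropped (with a message reporting
#' the count) and all other tags are ignored. Only `is_a` links are loaded:
#' `part_of` and other relationship types are not propagated.
#'
#' @param path path to an OBO file
#' @param namespace if given, restrict to this namespace and fail if any
#'   `is_a` link crosses out of it (each run is single-namespace)
#' @return an [ontology()]
#' @export
read_obo <- function(path, namespace = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", trimws(lines))
  if (length(term_starts) == 0) stop("no [Term] stanzas in ", path)
  ends <- c(stanza_starts[-1] - 1, length(lines))
  names(ends) <- NULL
  terms <- list(); parents <- list(); n_obsolete <- 0L
  for (k in seq_along(stanza_starts)) {
    if (!(stanza_starts[k] %in% term_starts)) next
    block <- lines[stanza_starts[k]:ends[k]]
    grab <- function(tag) {
      v <- grep(paste0("^", tag, ":"), block, value = TRUE)
      trimws(sub(paste0("^", tag, ":\\s*"), "", v))
    }
    id <- grab("id")[1]
    if (is.na(id)) next
    if (any(grab("is_obsolete") == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    nm <- grab("name")[1]
    ns <- grab("namespace")[1]
    isa <- grab("is_a")
    # "is_a: GO:0003674 ! molecular_function" -> id before comment
    isa <- trimws(sub("!.*$", "", isa))
    terms[[id]] <- data.frame(id = id,
                              name = if (is.na(nm)) id else nm,
                              namespace = if (is.na(ns)) "" else ns,
                              stringsAsFactors = FALSE)
    if (length(isa) > 0) parents[[id]] <- isa
  }
  if (n_obsolete > 0)
    message("dropped ", n_obsolete, " obsolete term(s)")
  term_df <- do.call(rbind, terms)
  if (!is.null(namespace)) {
    inside <- term_df$id[term_df$namespace == namespace]
    cross <- unlist(lapply(inside, function(t)
      setdiff(parents[[t]], inside)), use.names = FALSE)
    if (length(cross) > 0)
      stop("is_a link(s) cross out of namespace '", namespace, "': ",
           paste(utils::head(unique(cross), 5), collapse = ", "))
    term_df <- term_df[term_df$id %in% inside, , drop = FALSE]
    parents <- parents[names(parents) %in% inside]
  } else {
    # drop dangling is_a links to terms not defined in the file
    parents <- lapply(parents, function(p) intersect(p, term_df$id))
    parents <- parents[vapply(parents, length, integer(1)) > 0]
  }
  ontology(term_df, parents)
}

#' Write an ontology as an OBO 1.2 flat file
#' @param o an [ontology()]
#' @param path output path
#' @export
write_obo <- function(o, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(o$terms))) {
    id <- o$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", o$terms$name[i]),
                 paste0("namespace: ", o$terms$namespace[i]),
                 paste0("is_a: ", o$parents[[id]])[length(o$parents[[id]]) > 0],
                 ""), con)
  }
  invisible(path)
}
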