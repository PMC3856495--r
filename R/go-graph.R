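#' Gene Ontology graphs
#'
#' A `go_graph` holds terms from the three GO namespaces
#' (biological_process, molecular_function, cellular_component) with
#' their `is_a` parents.  Only `is_a` edges are represented; other
#' relations in an input file are ignored.  The graph must be acyclic
#' and every term must reach its namespace root.
#'
#' @param terms data.frame with columns id, name, namespace.
#' @param parents named list: term id -> character vector of parent ids.
#' @return A list of class `go_graph` with elements `terms`, `parents`
#'   and `roots` (named by namespace).
#' @export
go_graph <- function(terms, parents) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  unknown <- setdiff(unlist(parents, use.names = FALSE), terms$id)
  if (length(unknown))
    stop("is_a parent not defined in graph: ", unknown[1L], call. = FALSE)
  g <- structure(list(terms = terms, parents = parents, roots = NULL),
                 class = "go_graph")
  ord <- topo_order(g)   # errors on cycles
  roots <- terms$id[lengths(parents) == 0L]
  ns <- terms$namespace[match(roots, terms$id)]
  if (anyDuplicated(ns))
    stop("namespace with more than one root term", call. = FALSE)
  g$roots <- setNames(roots, ns)
  # every term must reach its namespace root
  anc <- go_ancestors(g, terms$id)
  reach <- mapply(function(id, a) {
    root <- g$roots[[terms$namespace[match(id, terms$id)]]]
    root %in% c(id, a)
  }, terms$id, anc)
  if (!all(reach))
    stop("term does not reach its namespace root: ",
         terms$id[!reach][1L], call. = FALSE)
  g
}

#' @export
print.go_graph <- function(x, ...) {
  cat("go_graph:", nrow(x$terms), "terms;",
      paste(sprintf("%s=%d", names(table(x$terms$namespace)),
                    table(x$terms$namespace)), collapse = ", "), "\n")
  invisible(x)
}

# Kahn topological order (leaves of is_a point to parents, so we order
# by number of unresolved parents); errors if a cycle exists.
topo_order <- function(graph) {
  ids <- graph$terms$id
  np <- lengths(graph$parents)
  children <- split(rep(ids, np), unlist(graph$parents, use.names = FALSE))
  indeg <- setNames(np, ids)
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]] %||% character()) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids))
    stop("cycle detected in is_a relations", call. = FALSE)
  out
}

#' Ancestors of GO terms
#'
#' Strict `is_a` ancestors (the term itself is not included).
#'
#' @param graph a [go_graph()].
#' @param ids term ids.
#' @return Named list of character vectors.
#' @export
go_ancestors <- function(graph, ids) {
  memo <- new.env(parent = emptyenv())
  anc1 <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- graph$parents[[id]]
    res <- if (!length(ps)) character() else
      unique(c(ps, unlist(lapply(ps, anc1), use.names = FALSE)))
    memo[[id]] <- res
    res
  }
  miss <- setdiff(ids, names(graph$parents))
  if (length(miss))
    stop("term not in graph: ", miss[1L], call. = FALSE)
  setNames(lapply(ids, anc1), ids)
}

#' Read a minimal OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas for id, name, namespace and `is_a` lines;
#' obsolete terms are skipped; any other relationship lines are
#' ignored.  A cycle in the `is_a` relations is a format error.
#'
#' @param path OBO file path.
#' @return A [go_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts))
    stop("no [Term] stanzas in OBO file: ", path, call. = FALSE)
  bounds <- c(term_starts, length(lines) + 1L)
  recs <- lapply(seq_along(term_starts), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "",
               grep(paste0("^", key, ": "), chunk, value = TRUE))
      if (length(v)) v[1L] else NA_character_
    }
    if (identical(get1("is_obsolete"), "true")) return(NULL)
    isa <- sub("\\s*!.*$", "",
               sub("^is_a: ", "", grep("^is_a: ", chunk, value = TRUE)))
    list(id = get1("id"), name = get1("name"),
         namespace = get1("namespace"), is_a = trimws(isa))
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  terms <- data.frame(id = vapply(recs, `[[`, "", "id"),
                      name = vapply(recs, `[[`, "", "name"),
                      namespace = vapply(recs, `[[`, "", "namespace"),
                      stringsAsFactors = FALSE)
  parents <- setNames(lapply(recs, `[[`, "is_a"), terms$id)
  # drop is_a references to terms absent from the file (e.g. obsolete)
  parents <- lapply(parents, function(p) p[p %in% terms$id])
  go_graph(terms, parents)
}

#' Write a minimal OBO 1.2 ontology
#'
#' @param graph a [go_graph()].
#' @param path output path.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", graph$terms$name[i]),
             paste0("namespace: ", graph$terms$namespace[i]),
             paste0("is_a: ", graph$parents[[id]]),
             "")
    writeLines(out, con)
  }
  invisible(path)
}
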