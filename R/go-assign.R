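#' Read and write GAF-style association files
#'
#' Only the columns used downstream are interpreted: column 2 (database
#' accession), column 5 (GO id) and column 9 (aspect code F/P/C).
#' Comment lines starting with `!` are skipped.
#'
#' @param path GAF file path.
#' @return `read_gaf()` returns a data.frame with columns accession,
#'   go_id, aspect.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines))
    return(data.frame(accession = character(), go_id = character(),
                      aspect = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9L)
  if (length(short))
    stop("GAF line ", short[1L], " has fewer than 9 columns", call. = FALSE)
  data.frame(accession = vapply(fields, `[[`, "", 2L),
             go_id = vapply(fields, `[[`, "", 5L),
             aspect = vapply(fields, `[[`, "", 9L),
             stringsAsFactors = FALSE)
}

#' @rdname read_gaf
#' @param goa data.frame with columns accession, go_id, aspect.
#' @export
write_gaf <- function(goa, path) {
  n <- nrow(goa)
  out <- cbind("DB", goa$accession, goa$accession, "",
               goa$go_id, "REF", "IEA", "", goa$aspect,
               "", "", "protein", "taxon:0", "20120601", "DB", "", "")
  writeLines(c("!gaf-version: 2.0",
               apply(out, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

# accession -> character vector of term ids
goa_as_map <- function(goa) {
  if (!nrow(goa)) return(structure(list(), names = character()))
  lapply(split(goa$go_id, goa$accession), unique)
}

#' Assign GO terms to contigs via best-hit accessions
#'
#' Each contig whose best hit came from a GO-bearing tier
#' (`annotated_flag`) receives the union of terms mapped to that hit's
#' accession.  Contigs whose accession is absent from the mapping get
#' no entry.
#'
#' @param annotation annotation data.frame from [tiered_annotate()]
#'   (or the `tiered_annotation` object itself).
#' @param goa a data.frame from [read_gaf()], or a named list
#'   accession -> term ids.
#' @return A named list of class `contig_go_map`: contig id -> distinct
#'   term ids.
#' @export
assign_go <- function(annotation, goa) {
  if (inherits(annotation, "tiered_annotation"))
    annotation <- annotation$annotation
  map <- if (is.data.frame(goa)) goa_as_map(goa) else goa
  ann <- annotation[annotation$annotated_flag, , drop = FALSE]
  hit <- ann$accession %in% names(map)
  out <- map[ann$accession[hit]]
  names(out) <- ann$contig_id[hit]
  structure(out, class = "contig_go_map")
}

#' @export
print.contig_go_map <- function(x, ...) {
  cat("contig_go_map:", length(x), "contigs,",
      sum(lengths(x)), "assignments,",
      length(unique(unlist(x, use.names = FALSE))), "distinct terms\n")
  invisible(x)
}

#' Per-namespace assignment summary for a contig GO map
#'
#' @param contig_go a `contig_go_map`.
#' @param graph a [go_graph()] supplying term namespaces.
#' @return data.frame with namespace, n_distinct_terms, n_assignments.
#' @export
go_map_summary <- function(contig_go, graph) {
  terms <- unlist(unclass(contig_go), use.names = FALSE)
  ns <- graph$terms$namespace[match(terms, graph$terms$id)]
  spaces <- sort(unique(graph$terms$namespace))
  data.frame(
    namespace = spaces,
    n_distinct_terms = vapply(spaces, function(s)
      length(unique(terms[ns == s])), 0L),
    n_assignments = vapply(spaces, function(s) sum(ns == s), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read and write contig GO maps as two-column TSV
#'
#' One `contig_id<TAB>term_id` row per assignment.
#'
#' @param path file path.
#' @return `read_go_map()` returns a `contig_go_map`.
#' @export
read_go_map <- function(path) {
  if (length(readLines(path)) < 2L)
    return(structure(setNames(list(), character()),
                     class = "contig_go_map"))
  df <- read.delim(path, header = TRUE,
                   colClasses = c("character", "character"))
  structure(lapply(split(df[[2L]], df[[1L]]), unique),
            class = "contig_go_map")
}

#' @rdname read_go_map
#' @param contig_go a `contig_go_map`.
#' @export
write_go_map <- function(contig_go, path) {
  m <- unclass(contig_go)
  df <- data.frame(contig_id = rep(names(m), lengths(m)),
                   term_id = unlist(m, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Project direct GO assignments onto a slim subset
#'
#' map2slim-style semantics: for each directly assigned term, the
#' contig receives the term's *closest* slim ancestors — slim terms
#' that are the term itself or ancestors of it, with no other slim
#' ancestor of the term lying strictly between them and the term
#' (equivalently, the minimal elements of the term's slim
#' ancestors-or-self under the is_a partial order).  Slim terms are
#' deduplicated per contig.
#'
#' @param graph a [go_graph()].
#' @param slim_ids slim term ids; must include each namespace root.
#' @param contig_go a `contig_go_map` of direct assignments.
#' @return A `contig_go_map` of slim assignments.
#' @export
map_to_slim <- function(graph, slim_ids, contig_go) {
  if (!all(slim_ids %in% graph$terms$id))
    stop("slim term not in graph: ",
         setdiff(slim_ids, graph$terms$id)[1L], call. = FALSE)
  if (!all(graph$roots %in% slim_ids))
    stop("slim set must contain every namespace root", call. = FALSE)
  direct <- unique(unlist(unclass(contig_go), use.names = FALSE))
  miss <- setdiff(direct, graph$terms$id)
  if (length(miss))
    stop("assigned term not in graph: ", miss[1L], call. = FALSE)
  anc_direct <- go_ancestors(graph, direct)
  # ancestors are also needed for the slim candidates themselves, to
  # test whether one slim ancestor lies below another
  anc <- go_ancestors(graph, unique(c(direct,
                                      unlist(anc_direct, use.names = FALSE))))
  slim_of <- lapply(direct, function(t) {
    s <- intersect(c(t, anc[[t]]), slim_ids)
    # drop any slim ancestor with another slim element below it
    keep <- vapply(s, function(x) {
      others <- setdiff(s, x)
      !any(vapply(others, function(y) x %in% anc[[y]], TRUE))
    }, TRUE)
    s[keep]
  })
  names(slim_of) <- direct
  out <- lapply(unclass(contig_go), function(terms)
    unique(unlist(slim_of[terms], use.names = FALSE)))
  structure(out, class = "contig_go_map")
}
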