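#' Clustering parameters
#'
#' Thresholds for redundancy clustering: contigs are linked when a
#' similarity hit shows at least `min_identity` percent nucleotide
#' identity over at least `min_coverage` of the shorter contig's length,
#' at `evalue_cutoff` or better.  Contigs below `min_length` are removed
#' before clustering.
#'
#' @param min_identity percent identity threshold (default 95).
#' @param min_coverage fraction of the shorter contig that must be
#'   covered by the alignment (default 0.70).
#' @param evalue_cutoff e-value cutoff for hits (default 1e-9).
#' @param min_length minimum contig length in nt (default 100).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(min_identity = 95, min_coverage = 0.70,
                           evalue_cutoff = 1e-9, min_length = 100L) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 1,
            evalue_cutoff > 0, min_length >= 0)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 evalue_cutoff = evalue_cutoff,
                 min_length = as.integer(min_length)),
            class = "cluster_params")
}

#' Remove contigs shorter than a minimum length
#'
#' Retains exactly the contigs with length >= `min_length` ("shorter
#' than" is exclusive), preserving input order.
#'
#' @param contigs a [contig_set()].
#' @param params a [cluster_params()] (only `min_length` is used).
#' @return The filtered [contig_set()].
#' @export
filter_min_length <- function(contigs, params = cluster_params()) {
  keep <- contig_lengths(contigs) >= params$min_length
  contigs[keep]
}

#' Group contigs into redundancy clusters
#'
#' A qualifying edge exists between two contigs iff some hit between
#' them has `pident >= min_identity` and alignment length
#' `>= min_coverage` times the length of the *shorter* contig (the
#' shorter of a redundant pair is the fragment the longest-representative
#' rule discards, so coverage is judged against it).  Clusters are the
#' connected components of the qualifying-edge graph (single linkage);
#' every contig appears, singletons as size-1 clusters.  The
#' representative is the longest member, ties broken by
#' lexicographically smallest id.
#'
#' @param hits a hit table as returned by [pairwise_hits()] or
#'   [read_hit_table()].
#' @param contigs a [contig_set()] containing every id in `hits`.
#' @param params a [cluster_params()].
#' @return A list of class `cluster_set` with elements `clusters`
#'   (list of member-id vectors), `representatives` (one id per
#'   cluster) and `members` (a data.frame of representative_id,
#'   member_id, member_length).
#' @export
build_clusters <- function(hits, contigs, params = cluster_params()) {
  ids <- names(contigs)
  n <- length(ids)
  len <- contig_lengths(contigs)
  idx <- seq_len(n); names(idx) <- ids

  if (nrow(hits)) {
    unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), ids)
    if (length(unknown))
      stop("hit references unknown contig: ", unknown[1L], call. = FALSE)
    self <- hits$qseqid == hits$sseqid
    h <- hits[!self, , drop = FALSE]
    shorter <- pmin(len[h$qseqid], len[h$sseqid])
    qual <- h$pident >= params$min_identity &
      h$length >= params$min_coverage * shorter &
      h$evalue <= params$evalue_cutoff
    h <- h[qual, , drop = FALSE]
  } else h <- hits

  # disjoint-set union with path compression
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <- root; i <- nxt }
    parent <<- parent
    root
  }
  if (nrow(h)) {
    qi <- idx[h$qseqid]; si <- idx[h$sseqid]
    for (e in seq_along(qi)) {
      a <- find(qi[e]); b <- find(si[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(ids, roots)
  names(comp) <- NULL
  reps <- vapply(comp, function(mem) {
    ml <- len[mem]
    cand <- mem[ml == max(ml)]
    sort(cand)[1L]
  }, "")
  ord <- order(reps)
  comp <- comp[ord]; reps <- reps[ord]
  members <- data.frame(
    representative_id = rep(reps, lengths(comp)),
    member_id = unlist(comp, use.names = FALSE),
    member_length = unname(len[unlist(comp, use.names = FALSE)]),
    stringsAsFactors = FALSE)
  structure(list(clusters = comp, representatives = reps, members = members),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("cluster_set:", length(x$clusters), "clusters over", sum(sizes),
      "contigs;", sum(sizes > 1L), "multi-member\n")
  invisible(x)
}

#' Keep one representative contig per cluster
#'
#' @param clusters a `cluster_set` from [build_clusters()].
#' @param contigs the [contig_set()] the clusters partition.
#' @return A [contig_set()] with one contig per cluster (the cluster's
#'   longest member).
#' @export
select_representatives <- function(clusters, contigs) {
  contigs[clusters$representatives]
}

#' Write a cluster membership table
#'
#' Tab-separated columns: representative_id, member_id, member_length.
#' @param clusters a `cluster_set`.
#' @param path output path.
#' @export
write_clusters <- function(clusters, path) {
  write.table(clusters$members, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
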