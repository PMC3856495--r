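# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: alignment by full dynamic programming
# (Biostrings), Fisher p by direct enumeration with choose(), BH by the
# naive O(m^2) definition, components by breadth-first search on an
# explicit adjacency matrix.

# Full local-alignment identity between two sequences (DP, no seeding).
oracle_align <- function(x, y) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  cols <- Biostrings::nchar(pa)
  list(identity = 100 * Biostrings::nmatch(pa) / cols, aln_length = cols)
}

# O(n^2) DP clustering oracle: qualifying edges from oracle_align,
# components by BFS over the adjacency matrix.
oracle_clusters <- function(contigs, min_identity = 95,
                            min_coverage = 0.70) {
  ids <- names(contigs)
  n <- length(ids)
  len <- nchar(unclass(contigs))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    al <- oracle_align(contigs[[i]], contigs[[j]])
    if (al$identity >= min_identity &&
        al$aln_length >= min_coverage * min(len[i], len[j]))
      adj[i, j] <- adj[j, i] <- TRUE
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; comp <- integer()
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE; comp <- c(comp, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- sort(ids[comp])
  }
  comps
}

# canonical string form of a partition, for set comparison
partition_key <- function(groups) {
  sort(vapply(lapply(groups, sort), paste, "", collapse = ","))
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins, probabilities from choose() directly.
oracle_fisher <- function(a, nA, b, nB) {
  m <- a + b
  if (m == 0 || nA == 0 || nB == 0 || m == nA + nB) return(1)
  k <- max(0, m - nB):min(m, nA)
  logp <- lchoose(nA, k) + lchoose(nB, m - k) - lchoose(nA + nB, m)
  p <- exp(logp)
  pobs <- exp(lchoose(nA, a) + lchoose(nB, m - a) - lchoose(nA + nB, m))
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# Naive O(m^2) Benjamini-Hochberg step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  q
}

# tiny convenience: build a go_graph from an edge list "child->parent"
toy_graph <- function(edges, namespaces) {
  ids <- names(namespaces)
  parents <- setNames(vector("list", length(ids)), ids)
  for (e in edges) {
    kv <- strsplit(e, "->", fixed = TRUE)[[1L]]
    parents[[kv[1L]]] <- c(parents[[kv[1L]]], kv[2L])
  }
  go_graph(data.frame(id = ids, name = ids,
                      namespace = unname(namespaces),
                      stringsAsFactors = FALSE),
           parents)
}
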