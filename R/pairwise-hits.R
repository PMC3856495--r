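# Built-in small-scale similarity search used to cluster synthetic
# contig sets and fixtures.  It is a same-strand, substitution-aware
# seeded search: shared k-mers nominate (pair, diagonal) candidates and
# each candidate is scored by the best ungapped segment along that
# diagonal.  Production-scale data uses an external 12-column hit table
# (see read_hit_table) computed by a full search tool; both paths feed
# build_clusters.

# map A/C/G/T -> 0..3, anything else (N) -> NA
.code_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut
})

seq_codes <- function(seq) .code_lut[utf8ToInt(seq)]

# integer codes of all k-mers of a sequence (NA where any base is N)
kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer())
  m <- n - k + 1L
  out <- integer(m)
  for (j in seq_len(k)) out <- out * 4L + codes[j:(j + m - 1L)]
  out
}

# Karlin-Altschul ungapped parameters for match +2 / mismatch -3
.ka_lambda <- 0.625
.ka_k <- 0.41

#' All-vs-all similarity hits by seeded ungapped extension
#'
#' For every ordered contig pair sharing at least `min_diag_seeds`
#' k-mers on one diagonal, the best-scoring ungapped segment along that
#' diagonal (match +2, mismatch -3) is reported as a hit: identity is
#' matches / alignment columns x 100, and hits whose bitscore-derived
#' e-value proxy exceeds `evalue_cutoff` are dropped.  Self-hits are
#' excluded and each qualifying pair is reported in both orientations.
#'
#' This is the package's testing stand-in for a full sequence search:
#' it assumes co-linear, same-strand redundancy (substitutions, prefix
#' truncations) as planted by [gen_contigs()], and does not model
#' indels or reverse-complement matches.  At scale, ingest an external
#' hit table with [read_hit_table()] instead.
#'
#' @param contigs a [contig_set()].
#' @param params a [cluster_params()] (only `evalue_cutoff` is used here).
#' @param k seed k-mer length (default 11).
#' @param min_diag_seeds number of shared same-diagonal k-mers required
#'   to nominate a pair (default 2; a 95%-identity overlap of >= 100 nt
#'   shares dozens).
#' @param max_kmer_occ k-mers occurring more often than this across the
#'   set are skipped as low-complexity/repetitive seeds.
#' @return A hit data.frame in the 12-column tabular dialect.
#' @export
pairwise_hits <- function(contigs, params = cluster_params(), k = 11L,
                          min_diag_seeds = 2L, max_kmer_occ = 50L) {
  n <- length(contigs)
  empty <- as.data.frame(setNames(
    c(list(character(), character()), rep(list(numeric()), 10L)), .hit_cols))
  if (n < 2L) return(empty)
  seqs <- unclass(contigs)
  ids <- names(contigs)
  codes <- lapply(seqs, seq_codes)
  lens <- lengths(codes)

  km <- lapply(codes, kmer_codes, k = as.integer(k))
  nk <- lengths(km)
  K <- unlist(km, use.names = FALSE)
  C <- rep.int(seq_len(n), nk)
  P <- unlist(lapply(nk, seq_len), use.names = FALSE)
  ok <- !is.na(K)
  K <- K[ok]; C <- C[ok]; P <- P[ok]
  if (!length(K)) return(empty)

  ord <- order(K, method = "radix")
  K <- K[ord]; C <- C[ord]; P <- P[ord]
  grp_end <- c(which(diff(K) != 0L), length(K))
  grp_start <- c(1L, head(grp_end, -1L) + 1L)
  gsize <- grp_end - grp_start + 1L
  keep <- gsize >= 2L & gsize <= max_kmer_occ

  # accumulate (pair, diagonal) seed counts
  pk <- vector("list", sum(keep)); dg <- pk
  t <- 0L
  Lmax <- max(lens)
  for (g in which(keep)) {
    sel <- grp_start[g]:grp_end[g]
    ci <- C[sel]; pi <- P[sel]
    gs <- length(sel)
    a <- rep(seq_len(gs), times = gs)
    b <- rep(seq_len(gs), each = gs)
    use <- ci[a] < ci[b]
    if (!any(use)) next
    t <- t + 1L
    pk[[t]] <- as.numeric(ci[a[use]]) * n + ci[b[use]]
    dg[[t]] <- pi[a[use]] - pi[b[use]]
  }
  if (t == 0L) return(empty)
  pk <- unlist(pk[seq_len(t)]); dg <- unlist(dg[seq_len(t)])

  key <- pk * (2 * Lmax + 1) + (dg + Lmax)
  okey <- order(key, method = "radix")
  key <- key[okey]; pk <- pk[okey]; dg <- dg[okey]
  kend <- c(which(diff(key) != 0), length(key))
  kstart <- c(1L, head(kend, -1L) + 1L)
  seeds <- kend - kstart + 1L
  cand <- seeds >= min_diag_seeds
  if (!any(cand)) return(empty)
  cpair <- pk[kstart[cand]]; cdiag <- dg[kstart[cand]]; cseeds <- seeds[cand]
  # one diagonal per pair: the best-supported one
  obest <- order(cpair, -cseeds)
  cpair <- cpair[obest]; cdiag <- cdiag[obest]
  first <- !duplicated(cpair)
  cpair <- cpair[first]; cdiag <- cdiag[first]

  ci <- as.integer(cpair %/% n); cj <- as.integer(cpair %% n)
  fix <- cj == 0L
  ci[fix] <- ci[fix] - 1L; cj[fix] <- n

  rows <- vector("list", length(ci))
  for (e in seq_along(ci)) {
    i <- ci[e]; j <- cj[e]; d <- cdiag[e]
    p1 <- max(1L, 1L + d); p2 <- min(lens[i], lens[j] + d)
    if (p2 - p1 + 1L < k) next
    xi <- codes[[i]][p1:p2]
    xj <- codes[[j]][(p1 - d):(p2 - d)]
    mt <- !is.na(xi) & !is.na(xj) & xi == xj
    sc <- ifelse(mt, 2, -3)
    pre <- cumsum(sc)
    minpre <- cummin(c(0, pre[-length(pre)]))
    val <- pre - minpre
    end <- which.max(val)
    raw <- val[end]
    start <- which(c(0, pre) == minpre[end])[1L]  # position before segment
    seg <- start:end
    cols <- end - start + 1L
    matches <- sum(mt[seg])
    bits <- (.ka_lambda * raw - log(.ka_k)) / log(2)
    evalue <- as.numeric(lens[i]) * lens[j] * 2^(-bits)
    if (evalue > params$evalue_cutoff) next
    qs <- p1 + start - 1L; qe <- p1 + end - 1L
    rows[[e]] <- data.frame(
      qseqid = ids[i], sseqid = ids[j],
      pident = 100 * matches / cols, length = cols,
      mismatch = cols - matches, gapopen = 0L,
      qstart = qs, qend = qe, sstart = qs - d, send = qe - d,
      evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  mirror <- hits
  mirror[c("qseqid", "sseqid", "qstart", "qend", "sstart", "send")] <-
    hits[c("sseqid", "qseqid", "sstart", "send", "qstart", "qend")]
  out <- rbind(hits, mirror)
  rownames(out) <- NULL
  out[order(out$qseqid, out$sseqid), , drop = FALSE]
}
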