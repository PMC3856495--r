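# Random-sequence machinery shared by the generators.  Sequences are
# drawn uniformly over {A,C,G,T}; one bulk draw is sliced into contigs,
# which keeps generating tens of thousands of contigs fast.

.base_codes <- c(65L, 67L, 71L, 84L)  # utf8 A C G T

random_seqs <- function(lengths) {
  lengths <- as.integer(lengths)
  if (!length(lengths)) return(character())
  total <- sum(lengths)
  codes <- .base_codes[sample.int(4L, total, replace = TRUE)]
  full <- intToUtf8(codes)
  ends <- cumsum(lengths)
  substring(full, ends - lengths + 1L, ends)
}

# Substitute bases at `rate` per site; a substituted base is always a
# different one of {A,C,G,T} (never N).
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  codes <- utf8ToInt(seq)
  old <- codes[pos]
  repl <- vapply(old, function(b) sample(setdiff(.base_codes, b), 1L), 0L)
  codes[pos] <- repl
  intToUtf8(codes)
}

#' Generate assembled contigs with planted near-identical clusters
#'
#' Produces a contig set in which each planted cluster is one progenitor
#' sequence plus copies mutated at the configured per-site substitution
#' rate and truncated (as prefixes) to a fraction of the progenitor
#' length drawn from `member_len_range`; all other contigs are
#' independent random sequences.  Lengths follow a truncated log-normal
#' law; `n_short` contigs are forced below 100 nt for length-filter
#' bookkeeping.  The ground truth records the planted partition and, per
#' cluster, the representative a longest-member rule should select
#' (ties broken by lexicographically smallest id).
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `contigs` (a [contig_set()]) and `truth`
#'   (list with `clusters`, `representatives`, `short_ids`).
#' @examples
#' sim <- gen_contigs(sim_config(seed = 1, n_contigs = 50,
#'                               cluster_sizes = rep(2L, 5)))
#' length(sim$contigs)
#' @export
gen_contigs <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  empty <- list(contigs = contig_set(),
                truth = list(clusters = list(),
                             representatives = character(),
                             short_ids = character()))
  if (cfg$n_contigs == 0L) return(empty)
  with_seed(cfg$seed + .seed_offset[["contigs"]], {
    sizes <- cfg$cluster_sizes
    n_clusters <- length(sizes)
    n_members <- sum(sizes)
    n_base <- cfg$n_contigs - (n_members - n_clusters)

    lo <- cfg$length_range[1L]
    hi <- cfg$length_range[2L]
    if (cfg$n_short > 0L) lo <- max(lo, 100L)
    lens <- round(rlnorm(n_base, log(cfg$length_median), cfg$length_sdlog))
    lens <- as.integer(pmin(pmax(lens, lo), hi))
    if (cfg$n_short > 0L) {
      if (cfg$n_short > n_base)
        stop("n_short exceeds the number of independent contigs",
             call. = FALSE)
      short_idx <- sample.int(n_base, cfg$n_short)
      lens[short_idx] <- as.integer(sample(50:99, cfg$n_short,
                                           replace = TRUE))
    } else short_idx <- integer()

    # progenitors must be long enough that >=70% truncation stays
    # above the 100 nt length filter
    eligible <- setdiff(which(lens >= 150L), short_idx)
    if (n_clusters > length(eligible))
      stop("not enough long contigs to host ", n_clusters,
           " planted clusters", call. = FALSE)
    prog_idx <- if (n_clusters) sample(eligible, n_clusters) else integer()

    seqs <- random_seqs(lens)

    copies <- character(n_members - n_clusters)
    copy_of <- integer(length(copies))   # progenitor (cluster) index
    ci <- 0L
    for (j in seq_len(n_clusters)) {
      prog <- seqs[prog_idx[j]]
      plen <- lens[prog_idx[j]]
      for (m in seq_len(sizes[j] - 1L)) {
        ci <- ci + 1L
        frac <- runif(1L, cfg$member_len_range[1L], cfg$member_len_range[2L])
        keep <- max(100L, as.integer(round(frac * plen)))
        copies[ci] <- mutate_seq(substr(prog, 1L, min(keep, plen)),
                                 cfg$substitution_rate)
        copy_of[ci] <- j
      }
    }

    all_seqs <- c(seqs, copies)
    # cluster index per emitted sequence (0 = independent)
    memb <- integer(length(all_seqs))
    if (n_clusters) {
      memb[prog_idx] <- seq_len(n_clusters)
      memb[n_base + seq_along(copy_of)] <- copy_of
    }
    ord <- sample.int(length(all_seqs))
    all_seqs <- all_seqs[ord]
    memb <- memb[ord]
    was_short <- seq_along(all_seqs) %in% which(ord %in% short_idx)
    ids <- sprintf("contig%06d", seq_along(all_seqs))
    names(all_seqs) <- ids

    clusters <- list()
    reps <- character()
    if (n_clusters) {
      clusters <- split(ids[memb > 0L], memb[memb > 0L])
      names(clusters) <- NULL
      reps <- vapply(clusters, function(mem) {
        len <- nchar(all_seqs[mem])
        cand <- mem[len == max(len)]
        sort(cand)[1L]
      }, "")
    }
    list(contigs = contig_set(all_seqs),
         truth = list(clusters = clusters,
                      representatives = reps,
                      short_ids = ids[was_short]))
  })
}
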