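#' Generate tiered database hit tables with planted assignments
#'
#' Mirrors a tiered screening cascade: walking the tiers in order, each
#' contig still unmatched is assigned to tier t with the configured
#' fraction (`tier_fractions`, applied to the not-yet-matched pool) or
#' by drawing exactly `tier_counts[t]` contigs from the pool.  Each
#' assigned contig receives exactly one qualifying hit (e-value at or
#' below 1e-9) in its tier's table, against a synthetic accession
#' unique to the contig.
#'
#' @param contigs a [contig_set()] (only ids and lengths are used).
#' @param cfg a [sim_config()].
#' @return A list with `tables` (named list of hit data.frames, one per
#'   tier) and `truth` (list with `tier_of_contig`, a named integer
#'   vector, NA for unmatched, and `accession_of_contig`).
#' @export
gen_reference_tiers <- function(contigs, cfg) {
  cfg <- validate_sim_config(cfg)
  tiers <- cfg$tier_names
  counts <- cfg$tier_counts
  fracs <- cfg$tier_fractions
  if (is.null(counts) && is.null(fracs))
    stop("either tier_fractions or tier_counts must be set", call. = FALSE)
  n_tiers <- if (!is.null(counts)) length(counts) else length(fracs)
  if (length(tiers) < n_tiers)
    tiers <- c(tiers, sprintf("tier%d", seq_len(n_tiers)))[seq_len(n_tiers)]
  with_seed(cfg$seed + .seed_offset[["tiers"]], {
    ids <- names(contigs)
    len <- contig_lengths(contigs)
    pool <- ids
    tier_of <- setNames(rep(NA_integer_, length(ids)), ids)
    acc_of <- setNames(rep(NA_character_, length(ids)), ids)
    tables <- setNames(vector("list", n_tiers), tiers[seq_len(n_tiers)])
    for (t in seq_len(n_tiers)) {
      n_match <- if (!is.null(counts)) counts[t]
      else as.integer(round(fracs[t] * length(pool)))
      n_match <- min(n_match, length(pool))
      matched <- if (n_match > 0L) sample(pool, n_match) else character()
      tier_of[matched] <- t
      acc <- sprintf("%s_ACC%06d", toupper(substr(tiers[t], 1L, 2L)),
                     seq_along(matched))
      acc_of[matched] <- acc
      qlen <- len[matched]
      aln <- pmax(30L, as.integer(round(qlen * runif(n_match, 0.5, 0.9))))
      one <- rep(1L, n_match)
      tables[[t]] <- data.frame(
        qseqid = matched, sseqid = acc,
        pident = round(runif(n_match, 60, 99), 2),
        length = aln, mismatch = as.integer(round(aln * 0.1)),
        gapopen = 0L * one, qstart = one, qend = aln,
        sstart = one, send = aln,
        evalue = 10^runif(n_match, -60, -9),
        bitscore = round(runif(n_match, 80, 500), 1),
        stringsAsFactors = FALSE)
      pool <- setdiff(pool, matched)
    }
    list(tables = tables,
         truth = list(tier_of_contig = tier_of,
                      accession_of_contig = acc_of))
  })
}
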