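#' Annotation parameters
#'
#' @param evalue_cutoff e-value threshold; a hit at exactly the cutoff
#'   passes (default 1e-9; the cross-species EST comparison profile uses
#'   1e-8).
#' @param tier_names ordered database names, most specific first.
#' @param go_tiers names of the tiers whose hits carry functional (GO)
#'   annotation.  Later, less-descriptive tiers contribute to the
#'   expressed-gene tally only.  Defaults to the first two tiers.
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(evalue_cutoff = 1e-9,
                              tier_names = c("SwissProt", "TrEMBL"),
                              go_tiers = tier_names[seq_len(min(2L, length(tier_names)))]) {
  stopifnot(evalue_cutoff > 0, length(tier_names) >= 1L,
            all(go_tiers %in% tier_names))
  structure(list(evalue_cutoff = evalue_cutoff, tier_names = tier_names,
                 go_tiers = go_tiers),
            class = "annotation_params")
}

#' Best hit for one contig
#'
#' Among the hits at or below the e-value cutoff, returns the one with
#' maximal bitscore; ties are broken by minimal e-value, then by
#' lexicographically smallest subject accession.
#'
#' @param hits data.frame of hits for a single query contig.
#' @param params an [annotation_params()].
#' @return A one-row data.frame (contig_id, accession, evalue, bitscore)
#'   or NULL if no hit passes the cutoff.
#' @export
best_hit <- function(hits, params = annotation_params()) {
  if (!nrow(hits)) return(NULL)
  if (length(unique(hits$qseqid)) > 1L)
    stop("best_hit expects hits for a single query", call. = FALSE)
  h <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
  data.frame(contig_id = h$qseqid[1L], accession = h$sseqid[1L],
             evalue = h$evalue[1L], bitscore = h$bitscore[1L],
             stringsAsFactors = FALSE)
}

# Vectorized best-hit over a whole table: one row per query that has a
# passing hit, same tie rules as best_hit().
best_hits_all <- function(hits, params) {
  h <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
  if (!nrow(h)) return(h[0L, , drop = FALSE])
  h <- h[order(h$qseqid, -h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Tiered best-hit annotation across ordered databases
#'
#' Databases are screened most specific first: tier t is queried only
#' with the contigs unmatched by tiers earlier in the list, and each
#' matched contig receives its best hit within that tier.  The summary
#' reports, per tier, the number of contigs queried, matched, and the
#' percentage matched, plus the final unmatched count — the cascade
#' accounting conserves contigs: queried(t+1) = queried(t) - matched(t).
#'
#' @param contig_ids character vector of contigs to annotate.
#' @param tier_hit_tables named list of hit data.frames, one per tier,
#'   in the order of `params$tier_names`.
#' @param params an [annotation_params()].
#' @return A list of class `tiered_annotation`: `annotation` (data.frame
#'   contig_id, tier, tier_index, accession, evalue, bitscore,
#'   annotated_flag) and `summary` (data.frame tier, n_queried,
#'   n_matched, pct_matched) with attribute `n_unmatched_final`.
#' @export
tiered_annotate <- function(contig_ids, tier_hit_tables,
                            params = annotation_params()) {
  tiers <- params$tier_names
  if (is.null(names(tier_hit_tables)))
    names(tier_hit_tables) <- tiers[seq_along(tier_hit_tables)]
  if (!all(names(tier_hit_tables) %in% tiers))
    stop("tier table names must match params$tier_names", call. = FALSE)
  pool <- unique(as.character(contig_ids))
  ann <- vector("list", length(tiers))
  summ <- data.frame(tier = tiers, n_queried = 0L, n_matched = 0L,
                     pct_matched = 0, stringsAsFactors = FALSE)
  for (t in seq_along(tiers)) {
    summ$n_queried[t] <- length(pool)
    tab <- tier_hit_tables[[tiers[t]]]
    if (!is.null(tab) && nrow(tab)) {
      tab <- tab[tab$qseqid %in% pool, , drop = FALSE]
      bh <- best_hits_all(tab, params)
    } else bh <- NULL
    if (!is.null(bh) && nrow(bh)) {
      ann[[t]] <- data.frame(contig_id = bh$qseqid, tier = tiers[t],
                             tier_index = t, accession = bh$sseqid,
                             evalue = bh$evalue, bitscore = bh$bitscore,
                             annotated_flag = tiers[t] %in% params$go_tiers,
                             stringsAsFactors = FALSE)
      summ$n_matched[t] <- nrow(bh)
      pool <- setdiff(pool, bh$qseqid)
    }
    summ$pct_matched[t] <- if (summ$n_queried[t])
      100 * summ$n_matched[t] / summ$n_queried[t] else 0
  }
  annotation <- do.call(rbind, c(ann[!vapply(ann, is.null, TRUE)],
                                 list(make.row.names = FALSE)))
  if (is.null(annotation))
    annotation <- data.frame(contig_id = character(), tier = character(),
                             tier_index = integer(), accession = character(),
                             evalue = numeric(), bitscore = numeric(),
                             annotated_flag = logical(),
                             stringsAsFactors = FALSE)
  attr(summ, "n_unmatched_final") <- length(pool)
  structure(list(annotation = annotation, summary = summ,
                 unmatched = pool),
            class = "tiered_annotation")
}

#' @export
print.tiered_annotation <- function(x, ...) {
  cat("tiered annotation:", nrow(x$annotation), "contigs matched,",
      length(x$unmatched), "unmatched\n")
  s <- x$summary
  for (t in seq_len(nrow(s)))
    cat(sprintf("  %-12s %6d / %6d  (%.1f%%)\n", s$tier[t],
                s$n_matched[t], s$n_queried[t], s$pct_matched[t]))
  invisible(x)
}

#' Write the annotation table and tier summary
#'
#' The summary mirrors the usual screening-table layout: one row per
#' database with "contigs with hits / contigs queried" and the
#' percentage with hits.
#'
#' @param x a `tiered_annotation`.
#' @param annotation_path,summary_path output TSV paths (NULL to skip).
#' @export
write_annotation <- function(x, annotation_path = NULL, summary_path = NULL) {
  if (!is.null(annotation_path))
    write.table(x$annotation[, c("contig_id", "tier", "accession",
                                 "evalue", "bitscore")],
                annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- x$summary
    out <- data.frame(
      Database = s$tier,
      `Contigs with hits/Total number of sequences` =
        sprintf("%d / %d", s$n_matched, s$n_queried),
      `Percentage with hits` = sprintf("%.1f%%", s$pct_matched),
      check.names = FALSE)
    write.table(out, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(x)
}
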