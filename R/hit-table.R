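.hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send",
               "evalue", "bitscore")

#' Read and write similarity hit tables
#'
#' The 12-column tab-separated tabular dialect (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score).  Lines with the
#' wrong column count are rejected with their line number.
#'
#' @param path file path.
#' @return `read_hit_table()` returns a data.frame with the 12 standard
#'   columns, numeric fields parsed.
#' @export
read_hit_table <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || !length(nf)) {
    out <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)),
      .hit_cols))
    out$length <- integer()
    return(out)
  }
  bad <- which(nf != 12L)
  if (length(bad))
    stop("malformed hit table ", path, ": line ", bad[1L], " has ",
         nf[bad[1L]], " fields (expected 12)", call. = FALSE)
  df <- read.delim(path, header = FALSE, col.names = .hit_cols,
                   colClasses = c("character", "character",
                                  rep("numeric", 10L)),
                   quote = "", comment.char = "")
  df$length <- as.integer(df$length)
  for (col in c("mismatch", "gapopen", "qstart", "qend", "sstart", "send"))
    df[[col]] <- as.integer(df[[col]])
  df
}

#' @rdname read_hit_table
#' @param hits a hit data.frame with the 12 standard columns.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(.hit_cols %in% names(hits)))
  out <- hits[, .hit_cols, drop = FALSE]
  out$pident <- sprintf("%.3f", out$pident)
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  out$bitscore <- sprintf("%.1f", out$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Group a hit table by query
#'
#' @param hits a hit data.frame.
#' @return A named list of data.frames, one per distinct `qseqid`.
#' @export
group_hits <- function(hits) {
  if (!nrow(hits)) return(structure(list(), names = character()))
  split(hits, factor(hits$qseqid, levels = unique(hits$qseqid)))
}
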