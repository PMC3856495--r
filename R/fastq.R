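#' Read-cleaning parameters
#'
#' Defaults follow the single-end Illumina cleaning recipe: trim the
#' first 15 and last 6 nt, then discard reads containing any run of N,
#' reads with 90% or more of their (trimmed) bases below Sanger quality
#' 23, and reads containing all or part of the 64-nt adapter — "part"
#' meaning any adapter substring of at least `min_adapter_match` nt.
#'
#' @param trim_head,trim_tail nt removed from each end before testing.
#' @param q_threshold Phred threshold (bases *below* this are low
#'   quality).
#' @param q_fraction a read is discarded when the low-quality fraction
#'   is `>=` this value (inclusive).
#' @param adapter adapter sequence (up to 64 nt).
#' @param min_adapter_match minimum adapter substring length counted as
#'   contamination.
#' @param n_run_min minimum length of an N run (default 2).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(trim_head = 15L, trim_tail = 6L, q_threshold = 23L,
                      q_fraction = 0.90,
                      adapter = paste(rep("AGATCGGAAGAGCACACGTC", 4),
                                      collapse = ""),
                      min_adapter_match = 10L, n_run_min = 2L) {
  stopifnot(trim_head >= 0, trim_tail >= 0,
            q_fraction > 0, q_fraction <= 1,
            min_adapter_match >= 1, n_run_min >= 1)
  structure(list(trim_head = as.integer(trim_head),
                 trim_tail = as.integer(trim_tail),
                 q_threshold = as.integer(q_threshold),
                 q_fraction = q_fraction,
                 adapter = substr(toupper(adapter), 1L, 64L),
                 min_adapter_match = as.integer(min_adapter_match),
                 n_run_min = as.integer(n_run_min)),
            class = "qc_params")
}

#' Read and write FASTQ (Phred+33)
#'
#' Wrappers over Biostrings keeping sequences and quality strings as
#' parallel character vectors.
#'
#' @param path FASTQ file path.
#' @return `read_fastq()` returns a list of class `fastq_reads` with
#'   `id`, `seq` and `qual` character vectors.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  fastq_reads(id = sub("\\s.*$", "", names(ss)),
              seq = as.character(ss),
              qual = as.character(S4Vectors::mcols(ss)$qualities))
}

#' @rdname read_fastq
#' @param reads a `fastq_reads` object.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname read_fastq
#' @param id,seq,qual parallel character vectors.
#' @export
fastq_reads <- function(id, seq, qual) {
  if (length(seq) != length(qual) || length(id) != length(seq))
    stop("id, seq and qual must have equal length", call. = FALSE)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("quality string length mismatch for read ", id[bad[1L]],
         call. = FALSE)
  structure(list(id = unname(id), seq = unname(toupper(seq)),
                 qual = unname(qual)),
            class = "fastq_reads")
}

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads:", length(x$id), "reads\n")
  invisible(x)
}

#' @export
length.fastq_reads <- function(x) length(x$id)

# fraction of bases with Phred quality < threshold, per read
low_quality_fraction <- function(qual, threshold) {
  vapply(qual, function(q) {
    ph <- utf8ToInt(q) - 33L
    mean(ph < threshold)
  }, 0, USE.NAMES = FALSE)
}

# TRUE for reads containing any adapter substring of length >= minlen.
# Any longer match contains a length-minlen window, so testing all
# adapter windows of exactly minlen is sufficient.
has_adapter <- function(seqs, adapter, minlen) {
  nw <- nchar(adapter) - minlen + 1L
  if (nw < 1L) return(rep(FALSE, length(seqs)))
  hit <- rep(FALSE, length(seqs))
  for (w in seq_len(nw)) {
    todo <- !hit
    if (!any(todo)) break
    win <- substr(adapter, w, w + minlen - 1L)
    hit[todo] <- grepl(win, seqs[todo], fixed = TRUE)
  }
  hit
}

#' Clean sequencing reads
#'
#' Each read is trimmed (`trim_head` then `trim_tail`), then discarded
#' if its trimmed sequence contains a run of at least `n_run_min`
#' consecutive N, if the fraction of trimmed bases below `q_threshold`
#' is at least `q_fraction`, or if it contains the adapter or any
#' adapter substring of at least `min_adapter_match` nt.  Reasons are
#' attributed in that order (N run, low quality, adapter) for reads
#' with several defects.
#'
#' @param reads a `fastq_reads` object (see [read_fastq()]).
#' @param params a [qc_params()].
#' @return A list of class `qc_result`: `reads` (retained, trimmed
#'   `fastq_reads`) and `report` (list with `input`, `retained` and a
#'   named `discarded` vector by reason).
#' @export
clean_reads <- function(reads, params = qc_params()) {
  n <- length(reads$id)
  if (n && any(nchar(reads$seq) <= params$trim_head + params$trim_tail))
    stop("read shorter than trim_head + trim_tail", call. = FALSE)
  seq <- substr(reads$seq, params$trim_head + 1L,
                nchar(reads$seq) - params$trim_tail)
  qual <- substr(reads$qual, params$trim_head + 1L,
                 nchar(reads$qual) - params$trim_tail)
  n_run <- grepl(sprintf("N{%d,}", params$n_run_min), seq)
  lowq <- !n_run &
    low_quality_fraction(qual, params$q_threshold) >= params$q_fraction
  adap <- !n_run & !lowq &
    has_adapter(seq, params$adapter, params$min_adapter_match)
  drop <- n_run | lowq | adap
  keep <- !drop
  structure(list(
    reads = fastq_reads(reads$id[keep], seq[keep], qual[keep]),
    report = list(input = n, retained = sum(keep),
                  discarded = c(n_run = sum(n_run),
                                low_quality = sum(lowq),
                                adapter = sum(adap)))),
    class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("clean_reads: %d in, %d retained (%.1f%%); discarded: %s\n",
              r$input, r$retained,
              if (r$input) 100 * r$retained / r$input else 100,
              paste(names(r$discarded), r$discarded, sep = "=",
                    collapse = ", ")))
  invisible(x)
}
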