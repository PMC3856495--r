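#' Contig sets
#'
#' A `contig_set` is a named character vector of uppercase nucleotide
#' sequences; names are contig identifiers, unique and nonempty.  It is
#' the unit flowing through length filtering, clustering and annotation.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @return A `contig_set`.
#' @examples
#' cs <- contig_set(c(c1 = "ACGTACGT", c2 = "ggttaacc"))
#' contig_lengths(cs)
#' @export
contig_set <- function(sequences = character()) {
  sequences <- setNames(as.character(sequences), names(sequences))
  if (length(sequences)) {
    ids <- names(sequences)
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
      stop("every contig must have a nonempty id", call. = FALSE)
    if (anyDuplicated(ids))
      stop("duplicate contig id: ", ids[duplicated(ids)][1L], call. = FALSE)
    if (any(!nzchar(sequences)))
      stop("empty sequence for contig: ", ids[!nzchar(sequences)][1L],
           call. = FALSE)
    sequences[] <- toupper(sequences)
  }
  structure(sequences, class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat("contig_set of", length(x), "sequences")
  if (length(x)) {
    len <- contig_lengths(x)
    cat(sprintf("; length %d-%d nt (mean %.0f)", min(len), max(len), mean(len)))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.contig_set` <- function(x, i) {
  contig_set(unclass(x)[i])
}

#' Contig lengths in nucleotides
#' @param contigs a [contig_set()].
#' @return Named integer vector of sequence lengths.
#' @export
contig_lengths <- function(contigs) {
  setNames(nchar(unclass(contigs)), names(contigs))
}

#' Read and write contig FASTA
#'
#' Thin wrappers over Biostrings.  Identifiers are the first
#' whitespace-delimited token of each header; sequences are uppercased.
#' `write_fasta()` wraps sequence lines at 70 columns, so a read/write
#' round trip preserves ids, order and sequences.
#'
#' @param path file path.
#' @return `read_fasta()` returns a [contig_set()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (length(seqs) && any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)][1L]
    stop("empty sequence in FASTA for record: ", bad, call. = FALSE)
  }
  names(seqs) <- ids
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  contig_set(seqs)
}

#' @rdname read_fasta
#' @param contigs a [contig_set()].
#' @export
write_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(unclass(contigs))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
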