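#' Transcript-by-library count matrices
#'
#' A `count_matrix` couples a non-negative transcript x library matrix
#' with a tissue label per library and a state flag (`raw` or
#' `normalized`).  Library ids are the column names; the convention for
#' files is a header of `tissue:library` names.
#'
#' @param counts numeric matrix, transcripts in rows, libraries in
#'   columns, with dimnames.
#' @param tissue character vector of tissue labels, one per library.
#' @param state "raw" or "normalized".
#' @return A list of class `count_matrix` with `counts`, `tissue`
#'   (named by library) and `state`.
#' @export
count_matrix <- function(counts, tissue, state = c("raw", "normalized")) {
  state <- match.arg(state)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and library colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("library ids must be unique", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(tissue) != ncol(counts))
    stop("one tissue label per library is required", call. = FALSE)
  structure(list(counts = counts,
                 tissue = setNames(as.character(tissue), colnames(counts)),
                 state = state),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix (%s): %d transcripts x %d libraries [%s]\n",
              x$state, nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$tissue)),
                            table(x$tissue)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read and write count matrices as TSV
#'
#' Rows are transcripts; the header row carries `tissue:library`
#' column names, from which tissue labels are recovered on read.
#'
#' @param path TSV path.
#' @return `read_counts()` returns a raw [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  cn <- colnames(df)
  if (!all(grepl(":", cn, fixed = TRUE)))
    stop("count matrix header must use tissue:library names", call. = FALSE)
  tissue <- sub(":.*$", "", cn)
  lib <- sub("^[^:]*:", "", cn)
  m <- as.matrix(df)
  colnames(m) <- lib
  count_matrix(m, tissue, state = "raw")
}

#' @rdname read_counts
#' @param cm a [count_matrix()].
#' @export
write_counts <- function(cm, path) {
  m <- cm$counts
  colnames(m) <- paste(cm$tissue, colnames(m), sep = ":")
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize libraries to the largest library total
#'
#' Counts in library `l` are multiplied by
#' `max_k(sum_k) / sum_l`, so every post-normalization library total
#' equals the largest pre-normalization total; the largest library is
#' unchanged.  Outputs are real-valued (no rounding).  Applying the
#' normalization twice is a no-op.
#'
#' @param cm a raw [count_matrix()]; every library sum must be positive.
#' @return The normalized [count_matrix()].
#' @export
normalize_counts <- function(cm) {
  sums <- colSums(cm$counts)
  if (any(sums == 0))
    stop("library has zero total counts: ",
         colnames(cm$counts)[sums == 0][1L], call. = FALSE)
  scaled <- sweep(cm$counts, 2L, max(sums) / sums, `*`)
  out <- count_matrix(scaled, cm$tissue, state = "raw")
  out$state <- "normalized"
  out
}

#' Expression-filter parameters
#'
#' A transcript is kept in a tissue's profile when it clears both a
#' per-library floor and a tissue-total floor on normalized counts:
#' with the default rule `"all"`, every library of the tissue must
#' reach `min_per_library` and the tissue total must exceed
#' `min_total` ("100 or fewer" is removed).  Rules `"any"` and
#' `"mean"` relax the per-library clause to at least one library,
#' or to the library mean.
#'
#' @param min_per_library per-library floor (default 10; "fewer than
#'   10" is removed).
#' @param min_total tissue-total floor (default 100; removal at
#'   `<= min_total`).
#' @param per_library_rule "all", "any" or "mean".
#' @return A list of class `expression_filter_params`.
#' @export
expression_filter_params <- function(min_per_library = 10,
                                     min_total = 100,
                                     per_library_rule = c("all", "any", "mean")) {
  per_library_rule <- match.arg(per_library_rule)
  stopifnot(min_per_library >= 0, min_total >= 0)
  structure(list(min_per_library = min_per_library, min_total = min_total,
                 per_library_rule = per_library_rule),
            class = "expression_filter_params")
}

#' Isolate a tissue's expression profile
#'
#' @param cm a normalized [count_matrix()].
#' @param tissue tissue label with at least one library.
#' @param params an [expression_filter_params()].
#' @return A list of class `tissue_profile`: `tissue`, `transcripts`
#'   (ids passing the filter), `counts` (their per-library normalized
#'   counts in this tissue) and `params`.
#' @export
filter_expression <- function(cm, tissue,
                              params = expression_filter_params()) {
  if (cm$state != "normalized")
    stop("filter_expression requires a normalized count matrix",
         call. = FALSE)
  libs <- names(cm$tissue)[cm$tissue == tissue]
  if (!length(libs)) stop("unknown tissue: ", tissue, call. = FALSE)
  sub <- cm$counts[, libs, drop = FALSE]
  total <- rowSums(sub)
  per_lib <- switch(params$per_library_rule,
                    all = apply(sub >= params$min_per_library, 1L, all),
                    any = apply(sub >= params$min_per_library, 1L, any),
                    mean = rowMeans(sub) >= params$min_per_library)
  keep <- per_lib & total > params$min_total
  structure(list(tissue = tissue,
                 transcripts = rownames(sub)[keep],
                 counts = sub[keep, , drop = FALSE],
                 params = params),
            class = "tissue_profile")
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("tissue_profile [%s]: %d expressed transcripts over %d libraries\n",
              x$tissue, length(x$transcripts), ncol(x$counts)))
  invisible(x)
}

#' Partition two tissue profiles into specific and shared sets
#'
#' @param profileA,profileB [filter_expression()] results built from
#'   the same normalized matrix.
#' @return A list of class `profile_partition`: `A_only`, `B_only`,
#'   `shared` (transcript id vectors) and `tissues`.
#' @export
partition_profiles <- function(profileA, profileB) {
  a <- profileA$transcripts; b <- profileB$transcripts
  structure(list(A_only = setdiff(a, b),
                 B_only = setdiff(b, a),
                 shared = intersect(a, b),
                 tissues = c(A = profileA$tissue, B = profileB$tissue)),
            class = "profile_partition")
}

#' @export
print.profile_partition <- function(x, ...) {
  cat(sprintf("partition [%s vs %s]: %d %s-only, %d %s-only, %d shared\n",
              x$tissues["A"], x$tissues["B"],
              length(x$A_only), x$tissues["A"],
              length(x$B_only), x$tissues["B"], length(x$shared)))
  invisible(x)
}

#' Correlation of shared-transcript expression between tissues
#'
#' Pearson correlation between the per-transcript summed normalized
#' counts in tissue A and tissue B, over the shared transcripts.
#'
#' @param partition a [partition_profiles()] result.
#' @param cm the normalized [count_matrix()] the profiles came from.
#' @return Pearson r.
#' @export
correlate_shared <- function(partition, cm) {
  shared <- partition$shared
  if (length(shared) < 3L)
    stop("need at least 3 shared transcripts", call. = FALSE)
  sums <- function(tissue) {
    libs <- names(cm$tissue)[cm$tissue == tissue]
    rowSums(cm$counts[shared, libs, drop = FALSE])
  }
  x <- sums(partition$tissues["A"]); y <- sums(partition$tissues["B"])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a tissue's shared-transcript counts",
         call. = FALSE)
  cor(x, y)
}

#' Most prevalent transcripts of a profile
#'
#' Transcripts ranked by tissue-summed normalized counts (descending,
#' ties by id), with each transcript's percentage of the profile's
#' total expression.
#'
#' @param profile a [filter_expression()] result.
#' @param k number of transcripts to report.
#' @return data.frame: transcript_id, total, percent_of_total.
#' @export
top_transcripts <- function(profile, k = 10L) {
  stopifnot(k >= 1L)
  total <- rowSums(profile$counts)
  ord <- order(-total, names(total))
  sel <- ord[seq_len(min(k, length(ord)))]
  data.frame(transcript_id = names(total)[sel],
             total = unname(total[sel]),
             percent_of_total = unname(100 * total[sel] / sum(total)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differentially expressed shared transcripts (pooled binomial screen)
#'
#' A deliberately simple stand-in for a moderated count-model DE test:
#' for each shared transcript, the tissue-A pooled normalized count is
#' tested against the binomial null whose proportion is implied by the
#' tissue library totals (after normalization, the number of libraries
#' per tissue), two-sided, followed by BH correction across the shared
#' transcripts.  The stage is pluggable: supply `external` to substitute
#' a DE call table computed elsewhere.
#'
#' @param partition a [partition_profiles()] result.
#' @param cm the normalized [count_matrix()].
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param external optional data.frame with columns transcript_id and
#'   p_adjusted from an external DE tool; if given, it is filtered to
#'   the shared set and thresholded instead.
#' @return A list of class `de_result`: `table` (transcript_id, count_A,
#'   count_B, p_raw, p_adjusted, de) and `de_ids`.
#' @export
de_shared <- function(partition, cm, alpha = 0.05, external = NULL) {
  shared <- partition$shared
  empty <- structure(list(
    table = data.frame(transcript_id = character(), count_A = numeric(),
                       count_B = numeric(), p_raw = numeric(),
                       p_adjusted = numeric(), de = logical(),
                       stringsAsFactors = FALSE),
    de_ids = character()), class = "de_result")
  if (!length(shared)) return(empty)
  if (!is.null(external)) {
    tab <- external[external$transcript_id %in% shared, , drop = FALSE]
    tab$de <- tab$p_adjusted <= alpha
    return(structure(list(table = tab,
                          de_ids = tab$transcript_id[tab$de]),
                     class = "de_result"))
  }
  libsA <- names(cm$tissue)[cm$tissue == partition$tissues["A"]]
  libsB <- names(cm$tissue)[cm$tissue == partition$tissues["B"]]
  if (length(libsA) < 2L || length(libsB) < 2L)
    stop("need at least two libraries per tissue", call. = FALSE)
  cA <- rowSums(cm$counts[shared, libsA, drop = FALSE])
  cB <- rowSums(cm$counts[shared, libsB, drop = FALSE])
  # Null proportion: tissue A's share of the shared-transcript pool.
  # With equal post-normalization library totals and no tissue-specific
  # expression this is the library-count ratio; anchoring it on the
  # shared pool additionally absorbs the composition shift that
  # tissue-specific transcripts impose on total-count normalization.
  p0 <- sum(cA) / (sum(cA) + sum(cB))
  x <- round(cA); tot <- round(cA) + round(cB)
  p <- vapply(seq_along(shared), function(i) {
    if (tot[i] == 0) return(1)
    binom.test(x[i], tot[i], p = p0)$p.value
  }, 0)
  p_adj <- bh_adjust(p)
  tab <- data.frame(transcript_id = shared, count_A = unname(cA),
                    count_B = unname(cB), p_raw = p, p_adjusted = p_adj,
                    de = p_adj <= alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, de_ids = tab$transcript_id[tab$de]),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x$table), "shared transcripts tested,",
      length(x$de_ids), "differentially expressed\n")
  invisible(x)
}

#' Write a tissue profile table
#'
#' Columns: transcript_id, tissue, per-library normalized counts,
#' total, percent_of_total.
#'
#' @param profile a `tissue_profile`.
#' @param path output TSV path.
#' @export
write_profile <- function(profile, path) {
  total <- rowSums(profile$counts)
  df <- data.frame(transcript_id = rownames(profile$counts),
                   tissue = profile$tissue,
                   profile$counts,
                   total = unname(total),
                   percent_of_total = unname(100 * total / sum(total)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
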