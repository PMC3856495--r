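#' Generate FASTQ reads with disjointly planted defects
#'
#' Produces `n_reads` single-end reads of `read_length` nt with
#' Phred+33 qualities.  Defects are planted in mutually exclusive read
#' subsets at the configured `contamination_fractions`, so retention
#' arithmetic is exact:
#'
#' * `adapter` — an adapter substring of at least the default minimum
#'   match length embedded inside the region that survives default
#'   trimming;
#' * `n_run` — a run of >= 2 consecutive N in the post-trim region;
#' * `low_quality` — all post-trim bases get qualities below 23 (so the
#'   >= 90% low-quality rule fires).
#'
#' Clean reads are rejection-sampled so that none trips any detector by
#' chance; their qualities lie in Q30-40.
#'
#' @param cfg a [sim_config()].
#' @param qc a [qc_params()] describing the cleaning rules the planted
#'   defects must (and clean reads must not) trigger.
#' @return A list with `reads` (a [fastq_reads()]) and `truth` (list
#'   with `defect_of_read`: named character, "none"/"adapter"/"n_run"/
#'   "low_quality").
#' @export
gen_reads <- function(cfg, qc = qc_params(adapter = cfg$adapter)) {
  cfg <- validate_sim_config(cfg)
  if (cfg$read_length <= qc$trim_head + qc$trim_tail)
    stop("read length must exceed trim_head + trim_tail", call. = FALSE)
  with_seed(cfg$seed + .seed_offset[["reads"]], {
    n <- cfg$n_reads
    rl <- cfg$read_length
    ids <- sprintf("read%06d", seq_len2(n))
    fr <- cfg$contamination_fractions
    n_def <- round(fr * n)
    # disjoint assignment of defects
    perm <- sample.int(n)
    i_ad <- perm[seq_len2(n_def[[1]])]
    i_nr <- perm[n_def[[1]] + seq_len2(n_def[[2]])]
    i_lq <- perm[n_def[[1]] + n_def[[2]] + seq_len2(n_def[[3]])]

    trim_lo <- qc$trim_head + 1L
    trim_hi <- rl - qc$trim_tail

    good_qual <- function(m) {
      q <- sample(30:40, m * rl, replace = TRUE) + 33L
      vapply(seq_len2(m), function(i)
        intToUtf8(q[((i - 1L) * rl + 1L):(i * rl)]), "")
    }
    # clean read pool, rejection-sampled against all three detectors
    make_clean <- function(m) {
      out <- character(m)
      need <- seq_len2(m)
      while (length(need)) {
        cand <- random_seqs(rep(rl, length(need)))
        trimmed <- substr(cand, trim_lo, trim_hi)
        ok <- !has_adapter(trimmed, qc$adapter, qc$min_adapter_match) &
          !grepl(sprintf("N{%d,}", qc$n_run_min), trimmed)
        out[need[ok]] <- cand[ok]
        need <- need[!ok]
      }
      out
    }

    seqs <- make_clean(n)
    quals <- good_qual(n)

    if (length(i_ad)) {
      match_len <- pmin(nchar(qc$adapter),
                        qc$min_adapter_match +
                          sample(0:20, length(i_ad), replace = TRUE))
      for (j in seq_along(i_ad)) {
        ml <- match_len[j]
        astart <- sample.int(nchar(qc$adapter) - ml + 1L, 1L)
        frag <- substr(qc$adapter, astart, astart + ml - 1L)
        pos <- sample(trim_lo:(trim_hi - ml + 1L), 1L)
        s <- seqs[i_ad[j]]
        seqs[i_ad[j]] <- paste0(substr(s, 1L, pos - 1L), frag,
                                substr(s, pos + ml, rl))
      }
    }
    if (length(i_nr)) {
      run_len <- sample(qc$n_run_min:(qc$n_run_min + 3L), length(i_nr),
                        replace = TRUE)
      for (j in seq_along(i_nr)) {
        ml <- run_len[j]
        pos <- sample(trim_lo:(trim_hi - ml + 1L), 1L)
        s <- seqs[i_nr[j]]
        seqs[i_nr[j]] <- paste0(substr(s, 1L, pos - 1L),
                                strrep("N", ml),
                                substr(s, pos + ml, rl))
      }
    }
    if (length(i_lq)) {
      # every post-trim base below the threshold => fraction 1 >= 0.9
      for (j in i_lq) {
        q <- utf8ToInt(quals[j])
        lowq <- sample(2:(qc$q_threshold - 1L), trim_hi - trim_lo + 1L,
                       replace = TRUE) + 33L
        q[trim_lo:trim_hi] <- lowq
        quals[j] <- intToUtf8(q)
      }
    }
    defect <- setNames(rep("none", n), ids)
    defect[i_ad] <- "adapter"
    defect[i_nr] <- "n_run"
    defect[i_lq] <- "low_quality"
    list(reads = fastq_reads(ids, seqs, quals),
         truth = list(defect_of_read = defect))
  })
}
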