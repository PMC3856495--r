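#' Incidence of GO terms in a transcriptome
#'
#' The incidence of a term is the number of distinct contigs carrying
#' it; a contig reached by a term via several paths counts once.  The
#' denominator is the number of contigs with at least one assignment
#' (the annotated set).
#'
#' @param contig_go a `contig_go_map`.
#' @param label transcriptome label.
#' @return A list of class `term_incidence` with `label`, `n_total`
#'   and `counts` (named integer vector).
#' @export
incidence <- function(contig_go, label = "transcriptome") {
  m <- unclass(contig_go)
  pairs <- unique(data.frame(
    contig = rep(names(m), lengths(m)),
    term = unlist(m, use.names = FALSE), stringsAsFactors = FALSE))
  counts <- if (nrow(pairs)) table(pairs$term) else table(character())
  structure(list(label = label, n_total = length(m),
                 counts = setNames(as.integer(counts), names(counts))),
            class = "term_incidence")
}

#' @export
print.term_incidence <- function(x, ...) {
  cat("term_incidence [", x$label, "]: ", length(x$counts),
      " terms over ", x$n_total, " contigs\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test on a 2x2 incidence table
#'
#' Tests independence on the table `[[a, nA-a], [b, nB-b]]` with the
#' uncorrected (no continuity correction) Pearson statistic and one
#' degree of freedom.  A degenerate table (any margin zero) returns
#' statistic 0 and p 1.  Vectorized over `a`, `b`, `nA`, `nB`.
#'
#' @param a,b term counts in transcriptomes A and B.
#' @param nA,nB total contigs in A and B.
#' @return A list with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(a, nA, b, nB) {
  if (any(c(a, b, nA, nB) < 0)) stop("negative counts", call. = FALSE)
  if (any(a > nA) || any(b > nB))
    stop("count exceeds its total", call. = FALSE)
  c1 <- a + b; c2 <- (nA - a) + (nB - b)
  N <- nA + nB
  stat <- ifelse(nA == 0 | nB == 0 | c1 == 0 | c2 == 0, 0,
                 N * (a * (nB - b) - b * (nA - a))^2 /
                   (as.numeric(nA) * nB * c1 * c2))
  p <- ifelse(stat == 0, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  list(statistic = stat, p = p)
}

#' Two-sided Fisher's exact test on a 2x2 incidence table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of
#' every table with the observed margins whose probability does not
#' exceed that of the observed table (with relative tolerance 1e-7 on
#' the comparison, as in the classical implementation).
#'
#' @inheritParams chi_square_2x2
#' @return Numeric vector of p-values (vectorized over inputs).
#' @export
fisher_2x2 <- function(a, nA, b, nB) {
  if (any(c(a, b, nA, nB) < 0)) stop("negative counts", call. = FALSE)
  if (any(a > nA) || any(b > nB))
    stop("count exceeds its total", call. = FALSE)
  n <- max(length(a), length(b), length(nA), length(nB))
  a <- rep_len(a, n); b <- rep_len(b, n)
  nA <- rep_len(nA, n); nB <- rep_len(nB, n)
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]                    # successes over both groups
    if (m == 0 || nA[i] == 0 || nB[i] == 0 || m == nA[i] + nB[i])
      return(1)
    k <- max(0, m - nB[i]):min(m, nA[i])
    d <- dhyper(k, m, nA[i] + nB[i] - m, nA[i])
    dobs <- dhyper(a[i], m, nA[i] + nB[i] - m, nA[i])
    min(1, sum(d[d <= dobs * (1 + 1e-7)]))
  }, 0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' For ascending p-values, the adjusted value is
#' `min over j >= i of p_(j) * m / j`, capped at 1, returned in the
#' original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Statistics parameters for incidence comparisons
#'
#' @param test "chi_square" or "fisher_exact".
#' @param alpha significance level on BH-adjusted p-values; the slim
#'   comparison uses 0.01, tissue-term and enrichment comparisons 0.05.
#' @param shared_terms_only test only terms with nonzero count in both
#'   transcriptomes.
#' @return A list of class `stats_params`.
#' @export
stats_params <- function(test = c("chi_square", "fisher_exact"),
                         alpha = 0.01, shared_terms_only = FALSE) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(test = test, alpha = alpha,
                 shared_terms_only = isTRUE(shared_terms_only)),
            class = "stats_params")
}

#' Compare per-term incidence between two transcriptomes
#'
#' One test per term; the BH family is the set of terms actually tested
#' in this call.  Significance uses `p_adjusted <= alpha`; direction
#' compares the proportions `a/nA` vs `b/nB`.  For chi-square tests a
#' `low_expected` flag marks tables with any expected cell below 5.
#'
#' @param incA,incB [incidence()] objects.
#' @param params a [stats_params()].
#' @return data.frame of class `term_comparison`: term_id, a, nA, b,
#'   nB, statistic, p_raw, p_adjusted, significant, direction,
#'   low_expected.
#' @export
compare_incidence <- function(incA, incB, params = stats_params()) {
  terms <- if (params$shared_terms_only)
    intersect(names(incA$counts)[incA$counts > 0],
              names(incB$counts)[incB$counts > 0])
  else union(names(incA$counts), names(incB$counts))
  terms <- sort(terms)
  a <- unname(ifelse(terms %in% names(incA$counts),
                     incA$counts[terms], 0L))
  b <- unname(ifelse(terms %in% names(incB$counts),
                     incB$counts[terms], 0L))
  a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
  nA <- incA$n_total; nB <- incB$n_total
  if (!length(terms)) {
    out <- data.frame(term_id = character(), a = integer(), nA = integer(),
                      b = integer(), nB = integer(), statistic = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      significant = logical(), direction = character(),
                      low_expected = logical(), stringsAsFactors = FALSE)
    class(out) <- c("term_comparison", "data.frame")
    return(out)
  }
  if (params$test == "chi_square") {
    ts <- chi_square_2x2(a, nA, b, nB)
    statistic <- ts$statistic; p_raw <- ts$p
  } else {
    statistic <- rep(NA_real_, length(terms))
    p_raw <- fisher_2x2(a, nA, b, nB)
  }
  # expected counts under independence, for the low-count flag
  N <- nA + nB
  m1 <- a + b; m0 <- N - m1
  expected_min <- pmin(m1 * nA, m1 * nB, m0 * nA, m0 * nB) / N
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(
    term_id = terms, a = a, nA = nA, b = b, nB = nB,
    statistic = statistic, p_raw = p_raw, p_adjusted = p_adj,
    significant = p_adj <= params$alpha,
    direction = ifelse(a / nA > b / nB, "over",
                       ifelse(a / nA < b / nB, "under", "equal")),
    low_expected = params$test == "chi_square" & expected_min < 5,
    stringsAsFactors = FALSE)
  class(out) <- c("term_comparison", "data.frame")
  out
}

#' Hypergeometric over-representation of GO terms in a gene subset
#'
#' Per term, the upper-tail hypergeometric p-value `P(X >= k)` with the
#' background contigs as the population, contigs carrying the term as
#' successes, the subset size as draws and the subset's term count as
#' the observation; BH-adjusted across all tested terms.
#'
#' @param subset_ids contig ids of the subset (must be contained in the
#'   background).
#' @param background_ids contig ids of the background population.
#' @param contig_go a `contig_go_map` covering (at least) the background.
#' @param alpha significance level on adjusted p-values.
#' @return data.frame: term_id, k (subset count), K (background count),
#'   n (subset size), N (background size), p_raw, p_adjusted,
#'   over_represented.
#' @export
hypergeom_enrichment <- function(subset_ids, background_ids, contig_go,
                                 alpha = 0.05) {
  subset_ids <- unique(subset_ids)
  background_ids <- unique(background_ids)
  if (!all(subset_ids %in% background_ids))
    stop("subset must be contained in the background", call. = FALSE)
  m <- unclass(contig_go)
  bg <- m[intersect(names(m), background_ids)]
  sub <- m[intersect(names(m), subset_ids)]
  Kc <- incidence(structure(bg, class = "contig_go_map"))$counts
  kc <- incidence(structure(sub, class = "contig_go_map"))$counts
  terms <- sort(names(kc))   # terms observed in the subset are tested
  if (!length(terms))
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), over_represented = logical(),
                      stringsAsFactors = FALSE))
  k <- kc[terms]; K <- Kc[terms]
  n <- length(subset_ids); N <- length(background_ids)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  data.frame(term_id = terms, k = unname(k), K = unname(K), n = n, N = N,
             p_raw = unname(p), p_adjusted = unname(p_adj),
             over_represented = unname(p_adj <= alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a term-comparison table
#'
#' @param comparison a `term_comparison` data.frame.
#' @param path output TSV path.
#' @param graph optional [go_graph()] to add term names and namespaces.
#' @export
write_comparison <- function(comparison, path, graph = NULL) {
  out <- comparison
  if (!is.null(graph)) {
    i <- match(out$term_id, graph$terms$id)
    out <- cbind(out[, "term_id", drop = FALSE],
                 name = graph$terms$name[i],
                 namespace = graph$terms$namespace[i],
                 out[, setdiff(names(out), "term_id")])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
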