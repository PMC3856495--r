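make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(n)
    strrep("I", n), "")   # I = Phred 40
  fastq_reads(sprintf("r%03d", seq_along(seqs)), seqs, quals)
}

test_that("read cleaning trims and applies the three discard rules", {
  set.seed(61)
  base <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  res <- clean_reads(make_reads(base))
  expect_equal(nchar(res$reads$seq), 79L)   # 100 - 15 - 6
  expect_equal(res$reads$seq, substr(base, 16, 94))

  # quality boundary: exactly 90% of trimmed bases below Q23 -> discarded
  q <- c(rep(20L, 71), rep(30L, 8))         # 71/79 = 0.899 < 0.9 kept
  qual_keep <- paste0(strrep("I", 15),
                      intToUtf8(q + 33L), strrep("I", 6))
  q90 <- c(rep(20L, 72), rep(30L, 7))       # 72/79 = 0.911 >= 0.9...
  # construct exact 90%: use 90 low of 100-21=79? use ceiling boundary
  expect_equal(clean_reads(make_reads(base, qual_keep))$report$retained, 1L)
  qual_drop <- paste0(strrep("I", 15),
                      intToUtf8(c(rep(20L, 72), rep(30L, 7)) + 33L),
                      strrep("I", 6))
  expect_equal(clean_reads(make_reads(base, qual_drop))$report$retained, 0L)

  # N run inside the trimmed region
  nn <- paste0(substr(base, 1, 40), "NN", substr(base, 43, 100))
  expect_equal(clean_reads(make_reads(nn))$report$discarded[["n_run"]], 1L)
  # single N is not a run at the default n_run_min = 2
  n1 <- paste0(substr(base, 1, 40), "N", substr(base, 42, 100))
  expect_equal(clean_reads(make_reads(n1))$report$retained, 1L)

  # adapter substring of >= 10 nt
  ad <- qc_params()$adapter
  with_ad <- paste0(substr(base, 1, 30), substr(ad, 5, 16),
                    substr(base, 43, 100))
  expect_equal(clean_reads(make_reads(with_ad))$report$discarded[["adapter"]],
               1L)

  expect_error(fastq_reads("r1", "ACGT", "III"), "length mismatch")
  expect_error(clean_reads(make_reads(strrep("A", 21))), "trim_head")
})

test_that("normalization equalizes library totals and is idempotent", {
  m <- matrix(c(10, 5, 990, 495), 2, 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("L1", "L2")))
  cm <- count_matrix(m, c("liver", "liver"))
  nm <- normalize_counts(cm)
  expect_equal(unname(nm$counts["t1", ]), c(10, 10))
  expect_equal(nm$state, "normalized")
  expect_equal(unname(colSums(nm$counts)), c(1000, 1000))

  # equal sums: unchanged
  m2 <- matrix(c(3, 7, 3, 7), 2, 2,
               dimnames = list(c("a", "b"), c("L1", "L2")))
  nm2 <- normalize_counts(count_matrix(m2, c("x", "y")))
  expect_equal(nm2$counts, m2)

  set.seed(8)
  big <- matrix(rpois(600, 40), 100, 6,
                dimnames = list(sprintf("t%03d", 1:100),
                                sprintf("L%d", 1:6)))
  nb <- normalize_counts(count_matrix(big, rep(c("liver", "gill"), each = 3)))
  sums <- colSums(nb$counts)
  expect_true(all(abs(sums - max(colSums(big))) / max(colSums(big)) < 1e-6))
  # idempotent: normalizing again changes nothing
  again <- nb; again$state <- "raw"
  expect_equal(normalize_counts(again)$counts, nb$counts, tolerance = 1e-12)

  zero <- matrix(c(1, 2, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("ok", "dead")))
  expect_error(normalize_counts(count_matrix(zero, c("x", "x"))), "dead")
})

test_that("expression filter applies per-library and total rules", {
  m <- matrix(c(0, 0, 0,
                40, 40, 40,
                5, 60, 60), 3, 3, byrow = TRUE,
              dimnames = list(c("zero", "solid", "uneven"),
                              c("L1", "L2", "L3")))
  cm <- count_matrix(m, rep("liver", 3))
  cm$state <- "normalized"
  all_rule <- filter_expression(cm, "liver")
  expect_equal(all_rule$transcripts, "solid")
  mean_rule <- filter_expression(
    cm, "liver", expression_filter_params(per_library_rule = "mean"))
  expect_setequal(mean_rule$transcripts, c("solid", "uneven"))
  any_rule <- filter_expression(
    cm, "liver", expression_filter_params(per_library_rule = "any"))
  expect_setequal(any_rule$transcripts, c("solid", "uneven"))

  # boundary: total exactly 100 is removed ("100 or fewer"), 10 per
  # library is kept ("fewer than 10" removed)
  mb <- matrix(c(10, 45, 45, 10, 45, 46), 2, 3, byrow = TRUE,
               dimnames = list(c("at100", "over100"), c("L1", "L2", "L3")))
  cmb <- count_matrix(mb, rep("liver", 3)); cmb$state <- "normalized"
  expect_equal(filter_expression(cmb, "liver")$transcripts, "over100")

  expect_error(filter_expression(cm, "kidney"), "unknown tissue")
  raw <- count_matrix(m, rep("liver", 3))
  expect_error(filter_expression(raw, "liver"), "normalized")

  # monotonicity: raising thresholds never adds transcripts
  set.seed(12)
  mm <- matrix(rpois(300, 30), 100, 3,
               dimnames = list(sprintf("t%03d", 1:100), c("a", "b", "c")))
  cmm <- count_matrix(mm, rep("gill", 3)); cmm$state <- "normalized"
  base <- filter_expression(cmm, "gill",
                            expression_filter_params(10, 80))$transcripts
  for (p in list(expression_filter_params(20, 80),
                 expression_filter_params(10, 120))) {
    expect_true(all(filter_expression(cmm, "gill", p)$transcripts %in% base))
  }
})

test_that("profile partition is a disjoint cover with exact planted sizes", {
  cfg <- sim_config(seed = 13, n_transcripts = 400, n_shared = 200,
                    n_specific = c(liver = 30, gill = 70))
  g <- gen_count_matrix(cfg)
  nm <- normalize_counts(g$matrix)
  pl <- filter_expression(nm, "liver")
  pg <- filter_expression(nm, "gill")
  part <- partition_profiles(pl, pg)
  expect_equal(length(part$A_only), 30L)
  expect_equal(length(part$B_only), 70L)
  expect_equal(length(part$shared), 200L)
  expect_setequal(part$shared, g$truth$shared)
  expect_setequal(part$A_only, g$truth$specific$liver)
  # disjoint cover of expressed(A) union expressed(B)
  expect_length(intersect(part$A_only, part$B_only), 0L)
  expect_length(intersect(part$A_only, part$shared), 0L)
  expect_setequal(c(part$A_only, part$shared), pl$transcripts)
  expect_setequal(c(part$B_only, part$shared), pg$transcripts)

  same <- partition_profiles(pl, pl)
  expect_length(same$A_only, 0L); expect_length(same$B_only, 0L)
})

test_that("shared-transcript correlation behaves on known structures", {
  ids <- sprintf("t%03d", 1:50)
  a <- seq(10, 500, length.out = 50)
  m <- cbind(A1 = a / 2, A2 = a / 2, B1 = a, B2 = a)
  rownames(m) <- ids
  cm <- count_matrix(m, c("liver", "liver", "gill", "gill"))
  cm$state <- "normalized"
  part <- structure(list(A_only = character(), B_only = character(),
                         shared = ids, tissues = c(A = "liver", B = "gill")),
                    class = "profile_partition")
  expect_equal(correlate_shared(part, cm), 1)

  rev <- cm
  rev$counts[, c("B1", "B2")] <- max(a) - rev$counts[, c("B1", "B2")] / 2
  expect_equal(correlate_shared(part, rev), -1)

  set.seed(4)
  n <- 2000
  x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  mm <- cbind(A1 = 1000 + 100 * x, B1 = 1000 + 100 * y, B2 = 0)
  rownames(mm) <- sprintf("s%04d", 1:n)
  cm2 <- count_matrix(pmax(mm, 0), c("liver", "gill", "gill"))
  cm2$state <- "normalized"
  part2 <- structure(list(shared = rownames(mm),
                          tissues = c(A = "liver", B = "gill")),
                     class = "profile_partition")
  expect_lt(abs(correlate_shared(part2, cm2) - 0.5), 0.05)

  flat <- cm
  flat$counts[, c("A1", "A2")] <- 5
  expect_error(correlate_shared(part, flat), "variance")
})

test_that("top transcripts rank by summed counts with id tie-breaks", {
  prof <- structure(list(tissue = "liver",
                         transcripts = c("one"),
                         counts = matrix(c(10, 20), 1, 2,
                                         dimnames = list("one", c("a", "b")))),
                    class = "tissue_profile")
  tt <- top_transcripts(prof, 5)
  expect_equal(tt$percent_of_total, 100)

  prof2 <- structure(list(tissue = "liver",
                          transcripts = c("b", "a"),
                          counts = matrix(c(15, 15, 15, 15), 2, 2,
                                          dimnames = list(c("b", "a"),
                                                          c("x", "y")))),
                     class = "tissue_profile")
  t2 <- top_transcripts(prof2, 2)
  expect_equal(t2$transcript_id, c("a", "b"))   # tie -> id order
  expect_equal(t2$percent_of_total, c(50, 50))
})

test_that("DE screen is null-calm, exact on planted folds, and pluggable", {
  # identical pooled counts: p = 1, nothing DE
  ids <- sprintf("t%03d", 1:20)
  m <- matrix(rep(c(50, 60, 70), each = 20), 20, 3)
  m <- cbind(m, m)
  dimnames(m) <- list(ids, sprintf("L%d", 1:6))
  cm <- count_matrix(m, rep(c("liver", "gill"), each = 3))
  cm$state <- "normalized"
  part <- structure(list(A_only = character(), B_only = character(),
                         shared = ids,
                         tissues = c(A = "liver", B = "gill")),
                    class = "profile_partition")
  res <- de_shared(part, cm)
  expect_true(all(res$table$p_raw == 1))
  expect_length(res$de_ids, 0L)

  # empty shared set
  none <- part; none$shared <- character()
  expect_length(de_shared(none, cm)$de_ids, 0L)

  # external table substitution
  ext <- data.frame(transcript_id = ids,
                    p_adjusted = c(0.001, rep(0.9, 19)))
  expect_equal(de_shared(part, cm, external = ext)$de_ids, ids[1])

  # planted 8-fold changes among NB noise are recovered (>= 90%)
  recov <- numeric(20)
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_transcripts = 2000, n_shared = 1900,
                      n_specific = c(liver = 50, gill = 50),
                      n_de = 50, de_fold_change = 8, nb_dispersion = 0.1,
                      mean_range = c(200, 400))
    g <- gen_count_matrix(cfg)
    nm <- normalize_counts(g$matrix)
    p <- partition_profiles(filter_expression(nm, "liver"),
                            filter_expression(nm, "gill"))
    de <- de_shared(p, nm)
    recov[seed] <- mean(g$truth$de_set %in% de$de_ids)
  }
  expect_true(all(recov >= 0.9))
})

test_that("DE screen controls FDR in its Poisson validity regime", {
  # Pure null: per-library Poisson counts around fixed means, equal
  # depths (the regime where the pooled binomial test is exact).
  set.seed(71)
  n_false <- 0L; n_tests <- 0L
  for (i in 1:20) {
    mu <- runif(200, 50, 500)
    m <- vapply(1:6, function(l) rpois(200, mu), numeric(200))
    dimnames(m) <- list(sprintf("t%03d", 1:200), sprintf("L%d", 1:6))
    cm <- count_matrix(m, rep(c("liver", "gill"), each = 3))
    cm$state <- "normalized"
    part <- structure(list(shared = rownames(m),
                           tissues = c(A = "liver", B = "gill")),
                      class = "profile_partition")
    res <- de_shared(part, cm, alpha = 0.05)
    n_false <- n_false + length(res$de_ids)
    n_tests <- n_tests + nrow(res$table)
  }
  expect_lte(n_false / n_tests, 0.05 + 2 * sqrt(0.05 * 0.95 / n_tests))
})

test_that("count matrices and FASTQ survive file round trips", {
  cfg <- sim_config(seed = 17, n_transcripts = 40, n_shared = 20,
                    n_specific = c(liver = 5, gill = 5), n_reads = 50)
  g <- gen_count_matrix(cfg)
  f <- tempfile(fileext = ".tsv")
  write_counts(g$matrix, f)
  back <- read_counts(f)
  expect_equal(back$counts, g$matrix$counts)
  expect_equal(back$tissue, g$matrix$tissue)

  r <- gen_reads(cfg)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(r$reads, fq)
  rb <- read_fastq(fq)
  expect_equal(rb$seq, r$reads$seq)
  expect_equal(rb$qual, r$reads$qual)
  expect_equal(rb$id, r$reads$id)
})
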