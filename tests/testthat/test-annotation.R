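test_that("hit tables round-trip and reject malformed lines", {
  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_hit_table(empty)), 0L)
  expect_length(group_hits(read_hit_table(empty)), 0L)

  hits <- data.frame(
    qseqid = c("q1", "q1", "q2"), sseqid = c("s1", "s2", "s1"),
    pident = c(98.5, 75.25, 100), length = c(120L, 80L, 500L),
    mismatch = c(1L, 20L, 0L), gapopen = c(0L, 2L, 0L),
    qstart = 1L, qend = c(120L, 80L, 500L), sstart = 1L,
    send = c(120L, 80L, 500L),
    evalue = c(1e-30, 2.5e-10, 0), bitscore = c(200.1, 90.5, 900),
    stringsAsFactors = FALSE)
  f <- tempfile()
  write_hit_table(hits, f)
  back <- read_hit_table(f)
  expect_equal(back$pident, hits$pident, tolerance = 1e-3)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-2)
  expect_equal(back$qseqid, hits$qseqid)
  expect_length(group_hits(back), 2L)
  expect_equal(nrow(group_hits(back)$q1), 2L)

  bad <- tempfile()
  writeLines(c(paste(rep("x", 12), collapse = "\t"),
               paste(rep("x", 7), collapse = "\t")), bad)
  expect_error(read_hit_table(bad), "line 2")
})

test_that("best hit maximizes bitscore with deterministic tie-breaking", {
  h <- data.frame(qseqid = "q", sseqid = c("accC", "accB", "accA"),
                  pident = 90, length = 100L, mismatch = 0L, gapopen = 0L,
                  qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
                  evalue = c(1e-10, 1e-30, 1e-20),
                  bitscore = c(50, 200, 200), stringsAsFactors = FALSE)
  expect_null(best_hit(h[0, ]))
  bh <- best_hit(h, annotation_params())
  expect_equal(bh$accession, "accB")   # bitscore tie -> smaller e-value
  expect_equal(bh$evalue, 1e-30)

  # cutoff is inclusive; nothing passing returns NULL
  h2 <- h; h2$evalue <- c(1e-9, 1e-8, 1e-8)
  expect_equal(best_hit(h2, annotation_params())$accession, "accC")

  # random tables equal an exhaustive scan oracle
  set.seed(42)
  for (rep in 1:5) {
    n <- 100L
    tab <- data.frame(qseqid = "q", sseqid = sprintf("acc%03d", sample(n)),
                      pident = 90, length = 100L, mismatch = 0L,
                      gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L,
                      send = 100L,
                      evalue = 10^runif(n, -40, -5),
                      bitscore = sample(50:90, n, TRUE),
                      stringsAsFactors = FALSE)
    got <- best_hit(tab, annotation_params())
    pass <- tab[tab$evalue <= 1e-9, ]
    if (!nrow(pass)) { expect_null(got); next }
    best <- pass[pass$bitscore == max(pass$bitscore), ]
    best <- best[best$evalue == min(best$evalue), ]
    expect_equal(got$accession, min(best$sseqid))
  }
})

test_that("tier cascade conserves contigs and queries only the unmatched", {
  cfg <- sim_config(seed = 12, n_contigs = 300,
                    tier_fractions = c(0.4, 0.25, 0.5),
                    tier_names = c("t1", "t2", "t3"))
  sim <- gen_contigs(cfg)
  tg <- gen_reference_tiers(sim$contigs, cfg)
  params <- annotation_params(tier_names = c("t1", "t2", "t3"),
                              go_tiers = c("t1", "t2"))
  res <- tiered_annotate(names(sim$contigs), tg$tables, params)
  s <- res$summary
  expect_equal(s$n_queried[1], 300L)
  for (t in 2:3)
    expect_equal(s$n_queried[t], s$n_queried[t - 1] - s$n_matched[t - 1])
  expect_equal(sum(s$n_matched) + attr(s, "n_unmatched_final"), 300L)
  # GO-bearing flag only on designated tiers
  expect_setequal(unique(res$annotation$tier[res$annotation$annotated_flag]),
                  intersect(c("t1", "t2"), res$annotation$tier))
  expect_false(any(res$annotation$annotated_flag[res$annotation$tier == "t3"]))

  # single tier matching everything
  cfg1 <- sim_config(seed = 12, n_contigs = 50, tier_fractions = 1,
                     tier_names = "only")
  sim1 <- gen_contigs(cfg1)
  tg1 <- gen_reference_tiers(sim1$contigs, cfg1)
  res1 <- tiered_annotate(names(sim1$contigs), tg1$tables,
                          annotation_params(tier_names = "only"))
  expect_equal(res1$summary$n_matched, 50L)
  expect_equal(attr(res1$summary, "n_unmatched_final"), 0L)
})

test_that("OBO reading handles chains, round trips and rejects cycles", {
  single <- tempfile()
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
               "name: root", "namespace: biological_process"), single)
  g1 <- read_obo(single)
  expect_equal(nrow(g1$terms), 1L)
  expect_equal(unname(g1$roots["biological_process"]), "GO:0000001")

  chain <- tempfile()
  writeLines(c("[Term]", "id: GO:1", "name: r", "namespace: bp", "",
               "[Term]", "id: GO:2", "name: m", "namespace: bp",
               "is_a: GO:1 ! r", "",
               "[Term]", "id: GO:3", "name: l", "namespace: bp",
               "is_a: GO:2", "",
               "[Term]", "id: GO:9", "name: gone", "namespace: bp",
               "is_a: GO:1", "is_obsolete: true"), chain)
  g <- read_obo(chain)
  expect_equal(nrow(g$terms), 3L)  # obsolete skipped
  expect_setequal(go_ancestors(g, "GO:3")[["GO:3"]], c("GO:2", "GO:1"))

  cyc <- tempfile()
  writeLines(c("[Term]", "id: GO:1", "name: a", "namespace: bp",
               "is_a: GO:2", "",
               "[Term]", "id: GO:2", "name: b", "namespace: bp",
               "is_a: GO:1"), cyc)
  expect_error(read_obo(cyc), "cycle")

  # generated DAG survives an OBO round trip structurally intact
  w <- gen_go_world(sim_config(seed = 31, n_go_terms = c(25L, 15L, 10L)))
  f <- tempfile()
  write_obo(w$graph, f)
  back <- read_obo(f)
  expect_equal(back$terms[order(back$terms$id), ],
               w$graph$terms[order(w$graph$terms$id), ],
               ignore_attr = TRUE)
  expect_identical(lapply(back$parents[w$graph$terms$id], sort),
                   lapply(w$graph$parents, sort))
})

test_that("GO assignment follows best-hit accessions through the GAF", {
  ann <- data.frame(contig_id = c("c1", "c2", "c3"),
                    tier = "t1", tier_index = 1L,
                    accession = c("P1", "P2", "P3"),
                    evalue = 1e-20, bitscore = 100,
                    annotated_flag = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  goa <- data.frame(accession = c("P1", "P1", "P2missing"),
                    go_id = c("GO:1", "GO:2", "GO:3"),
                    aspect = "P", stringsAsFactors = FALSE)
  m <- assign_go(ann, goa)
  expect_equal(names(m), "c1")            # P2 absent, c3 not GO-bearing
  expect_setequal(m$c1, c("GO:1", "GO:2"))
  expect_length(assign_go(ann, goa[0, ]), 0L)

  # GAF round trip preserves the mapping
  f <- tempfile()
  write_gaf(goa, f)
  expect_equal(read_gaf(f), goa, ignore_attr = TRUE)
})

test_that("slim projection returns closest slim ancestors", {
  # chain root -> a -> b, slim {root, a}: b maps to a
  g <- toy_graph(c("a->root", "b->a"),
                 c(root = "bp", a = "bp", b = "bp"))
  m <- structure(list(c1 = "b"), class = "contig_go_map")
  expect_equal(map_to_slim(g, c("root", "a"), m)$c1, "a")

  # term already in the slim maps to itself only
  m2 <- structure(list(c1 = "a"), class = "contig_go_map")
  expect_equal(map_to_slim(g, c("root", "a"), m2)$c1, "a")

  # diamond: b is_a a1 and a2, both slim -> both returned
  gd <- toy_graph(c("a1->root", "a2->root", "b->a1", "b->a2"),
                  c(root = "bp", a1 = "bp", a2 = "bp", b = "bp"))
  md <- structure(list(c1 = "b"), class = "contig_go_map")
  expect_setequal(map_to_slim(gd, c("root", "a1", "a2"), md)$c1,
                  c("a1", "a2"))

  expect_error(map_to_slim(g, "a", m), "namespace root")
  expect_error(map_to_slim(g, c("root", "zzz"), m), "not in graph")
})

test_that("slim projection is sound and minimal on random DAGs", {
  for (seed in c(8, 80)) {
    w <- gen_go_world(sim_config(seed = seed,
                                 n_go_terms = c(30L, 20L, 10L),
                                 slim_fraction = 0.25))
    g <- w$graph
    direct <- structure(
      list(c1 = sample(g$terms$id, 5), c2 = sample(g$terms$id, 3)),
      class = "contig_go_map")
    slimmed <- map_to_slim(g, w$slim_ids, direct)
    anc <- go_ancestors(g, g$terms$id)
    for (contig in names(direct)) {
      down <- direct[[contig]]
      up <- slimmed[[contig]]
      expect_true(all(up %in% w$slim_ids))
      # soundness: each slim term is ancestor-or-self of a direct term
      anc_or_self <- unique(c(down, unlist(anc[down])))
      expect_true(all(up %in% anc_or_self))
      # minimality per direct term: projecting t alone keeps no slim
      # ancestor that has another slim ancestor of t strictly below it
      for (t in down) {
        s_all <- intersect(c(t, anc[[t]]), w$slim_ids)
        one <- structure(list(x = t), class = "contig_go_map")
        up_t <- map_to_slim(g, w$slim_ids, one)$x
        expect_true(all(up_t %in% up))  # union consistency
        for (x in up_t)
          expect_false(any(vapply(setdiff(s_all, x), function(y)
            x %in% anc[[y]], TRUE)))
      }
    }
  }
})
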