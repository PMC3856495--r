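#' Run pipeline stages from a configuration
#'
#' Orchestrates the stages as one deterministic run: `simulate` writes
#' every synthetic input, then `clean_reads`, `cluster`, `annotate`
#' (tiered screening + GO assignment), `slim`, `profile`
#' (normalize/filter/partition) and `compare_go` consume files from the
#' output directory (or externally supplied paths).  A manifest records
#' the package version, the seed, every applied parameter and
#' per-stage input/output record counts, and is written as
#' `manifest.json` in the output directory.  Re-running with the same
#' configuration produces byte-identical outputs.
#'
#' The configuration is a nested list (or a YAML file path) with
#' top-level `seed`, `out`, `stages` (character vector in execution
#' order) and one section per stage; command-line flags of the
#' `coldref` script override file values.
#'
#' @param config nested configuration list, or path to a YAML file.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% character()
  manifest <- list(package = "coldref",
                   version = as.character(utils::packageVersion("coldref")),
                   seed = seed, stages = list())
  path_in <- function(stage_cfg, key, default)
    stage_cfg[[key]] %||% file.path(out_dir, default)

  for (stage in stages) {
    sc <- config[[stage]] %||% list()
    rec <- tryCatch(
      switch(stage,
        simulate = stage_simulate(sc, seed, out_dir),
        clean_reads = stage_clean_reads(sc, out_dir, path_in),
        cluster = stage_cluster(sc, out_dir, path_in),
        annotate = stage_annotate(sc, out_dir, path_in),
        slim = stage_slim(sc, out_dir, path_in),
        profile = stage_profile(sc, out_dir, path_in),
        compare_go = stage_compare_go(sc, out_dir, path_in),
        stop("unknown stage: ", stage, call. = FALSE)),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    rec$inputs_md5 <- as.list(rec$inputs_md5 %||% character())
    manifest$stages[[stage]] <- rec
    message(sprintf("[coldref] %-12s in=%s out=%s", stage,
                    rec$n_in %||% NA, rec$n_out %||% NA))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(sc, seed, out_dir) {
  args <- sc[setdiff(names(sc), "write")]
  cfg <- do.call(sim_config, c(list(seed = seed), args))
  sim <- gen_contigs(cfg)
  write_fasta(sim$contigs, file.path(out_dir, "contigs.fasta"))
  tiers <- gen_reference_tiers(sim$contigs, cfg)
  for (t in names(tiers$tables))
    write_hit_table(tiers$tables[[t]],
                    file.path(out_dir, paste0("hits_", t, ".tsv")))
  acc <- tiers$truth$accession_of_contig
  acc <- unname(acc[!is.na(acc)])
  world <- gen_go_world(cfg, accessions = if (length(acc)) acc)
  write_obo(world$graph, file.path(out_dir, "ontology.obo"))
  write_gaf(world$goa, file.path(out_dir, "annotations.gaf"))
  writeLines(world$slim_ids, file.path(out_dir, "slim_ids.txt"))
  counts <- gen_count_matrix(cfg)
  write_counts(counts$matrix, file.path(out_dir, "counts.tsv"))
  reads <- gen_reads(cfg)
  write_fastq(reads$reads, file.path(out_dir, "reads.fastq"))
  list(params = list(n_contigs = cfg$n_contigs,
                     n_transcripts = cfg$n_transcripts,
                     n_reads = cfg$n_reads),
       n_in = 0L, n_out = length(sim$contigs))
}

stage_clean_reads <- function(sc, out_dir, path_in) {
  fq <- path_in(sc, "fastq", "reads.fastq")
  params <- do.call(qc_params, sc[intersect(names(sc), names(formals(qc_params)))])
  res <- clean_reads(read_fastq(fq), params)
  write_fastq(res$reads, file.path(out_dir, "reads.clean.fastq"))
  rep <- res$report
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "clean_report.json"))
  list(params = unclass(params), inputs_md5 = tools::md5sum(fq),
       n_in = rep$input, n_out = rep$retained,
       discarded = as.list(rep$discarded))
}

stage_cluster <- function(sc, out_dir, path_in) {
  fa <- path_in(sc, "fasta", "contigs.fasta")
  params <- do.call(cluster_params,
                    sc[intersect(names(sc), names(formals(cluster_params)))])
  contigs <- read_fasta(fa)
  n_in <- length(contigs)
  contigs <- filter_min_length(contigs, params)
  hits <- if (!is.null(sc$hits)) read_hit_table(sc$hits)
          else pairwise_hits(contigs, params)
  cl <- build_clusters(hits, contigs, params)
  reps <- select_representatives(cl, contigs)
  write_fasta(reps, file.path(out_dir, "reference.fasta"))
  write_clusters(cl, file.path(out_dir, "clusters.tsv"))
  list(params = unclass(params), inputs_md5 = tools::md5sum(fa),
       n_in = n_in, n_after_length_filter = length(contigs),
       n_clusters = length(cl$clusters), n_out = length(reps))
}

stage_annotate <- function(sc, out_dir, path_in) {
  fa <- path_in(sc, "fasta", "reference.fasta")
  contigs <- read_fasta(fa)
  tier_paths <- sc$tiers
  if (is.null(tier_paths)) {
    found <- list.files(out_dir, pattern = "^hits_.*\\.tsv$",
                        full.names = TRUE)
    tier_paths <- setNames(as.list(found),
                           sub("^hits_(.*)\\.tsv$", "\\1", basename(found)))
  }
  params <- annotation_params(
    evalue_cutoff = sc$evalue %||% 1e-9,
    tier_names = names(tier_paths))
  tables <- lapply(tier_paths, read_hit_table)
  res <- tiered_annotate(names(contigs), tables, params)
  write_annotation(res, file.path(out_dir, "annotation.tsv"),
                   file.path(out_dir, "tier_summary.tsv"))
  goa_path <- path_in(sc, "goa", "annotations.gaf")
  contig_go <- assign_go(res, read_gaf(goa_path))
  write_go_map(contig_go, file.path(out_dir, "contig_go.tsv"))
  list(params = unclass(params),
       inputs_md5 = tools::md5sum(c(fa, unlist(tier_paths))),
       n_in = length(contigs), n_out = nrow(res$annotation),
       per_tier = setNames(as.list(res$summary$n_matched),
                           res$summary$tier),
       n_go_contigs = length(contig_go))
}

stage_slim <- function(sc, out_dir, path_in) {
  obo <- path_in(sc, "obo", "ontology.obo")
  slim_path <- path_in(sc, "slim", "slim_ids.txt")
  map_path <- path_in(sc, "go_map", "contig_go.tsv")
  graph <- read_obo(obo)
  contig_go <- read_go_map(map_path)
  slimmed <- map_to_slim(graph, readLines(slim_path), contig_go)
  write_go_map(slimmed, file.path(out_dir, "contig_go_slim.tsv"))
  list(inputs_md5 = tools::md5sum(c(obo, slim_path, map_path)),
       n_in = length(contig_go), n_out = length(slimmed))
}

stage_profile <- function(sc, out_dir, path_in) {
  cpath <- path_in(sc, "counts", "counts.tsv")
  cm <- normalize_counts(read_counts(cpath))
  params <- do.call(expression_filter_params,
                    sc[intersect(names(sc),
                                 names(formals(expression_filter_params)))])
  tissues <- sc$tissues %||% unique(unname(cm$tissue))
  profiles <- lapply(tissues, function(t)
    filter_expression(cm, t, params))
  names(profiles) <- tissues
  for (t in tissues)
    write_profile(profiles[[t]],
                  file.path(out_dir, paste0("profile_", t, ".tsv")))
  rec <- list(params = unclass(params), inputs_md5 = tools::md5sum(cpath),
              n_in = nrow(cm$counts),
              n_expressed = lapply(profiles, function(p)
                length(p$transcripts)))
  if (length(tissues) == 2L) {
    part <- partition_profiles(profiles[[1L]], profiles[[2L]])
    df <- data.frame(
      transcript_id = c(part$A_only, part$B_only, part$shared),
      class = rep(c(paste0(tissues[1L], "_only"),
                    paste0(tissues[2L], "_only"), "shared"),
                  c(length(part$A_only), length(part$B_only),
                    length(part$shared))))
    write.table(df[order(df$transcript_id), ],
                file.path(out_dir, "partition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rec$partition <- list(A_only = length(part$A_only),
                          B_only = length(part$B_only),
                          shared = length(part$shared))
    rec$n_out <- length(part$A_only) + length(part$B_only) +
      length(part$shared)
  } else rec$n_out <- sum(unlist(rec$n_expressed))
  rec
}

stage_compare_go <- function(sc, out_dir, path_in) {
  a_path <- path_in(sc, "a", "contig_go_slim.tsv")
  b_path <- sc$b
  if (is.null(b_path)) stop("compare_go needs a 'b' map path", call. = FALSE)
  params <- stats_params(test = sc$test %||% "chi_square",
                         alpha = sc$alpha %||% 0.01,
                         shared_terms_only = isTRUE(sc$shared_only))
  incA <- incidence(read_go_map(a_path), "A")
  incB <- incidence(read_go_map(b_path), "B")
  cmp <- compare_incidence(incA, incB, params)
  write_comparison(cmp, file.path(out_dir, "comparison.tsv"))
  list(params = unclass(params),
       inputs_md5 = tools::md5sum(c(a_path, b_path)),
       n_in = length(union(names(incA$counts), names(incB$counts))),
       n_out = nrow(cmp), n_significant = sum(cmp$significant))
}
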