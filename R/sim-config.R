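#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  The defaults
#' reproduce the study conditions the generators emulate: a contig
#' length distribution averaging roughly 920 +/- 700 nt on [50, 7000],
#' planted near-identical contig clusters at 1% within-cluster
#' substitution, tier match proportions shaped like a two-tier
#' SwissProt/TrEMBL cascade, a three-namespace GO world with a slim
#' subset, 3+3-library liver/gill count matrices with planted
#' 9,750 shared / 700 liver-only / 3,378 gill-only expressed transcripts
#' and negative-binomial noise, and 100-nt single-end reads with
#' disjointly planted adapter / N-run / low-quality defects.
#'
#' All generators are pure functions of the configuration: the same
#' `sim_config()` yields byte-identical outputs.  Randomness for each
#' generator is drawn from a private stream seeded at `seed` plus a
#' fixed per-generator offset, so adding one generator call never shifts
#' another's output.
#'
#' @param seed integer seed for all generators.
#' @param n_contigs number of contigs to generate.
#' @param length_median,length_sdlog log-normal length law (median nt and
#'   sdlog), truncated to `length_range`.
#' @param length_range inclusive truncation bounds in nt.
#' @param n_short number of contigs forced shorter than 100 nt (drawn
#'   uniformly on 50-99 nt), for length-filter bookkeeping fixtures.
#' @param cluster_sizes integer vector of planted cluster sizes (each >= 2);
#'   empty means no planted clusters.
#' @param substitution_rate per-site substitution probability within a
#'   planted cluster (never produces N).
#' @param member_len_range range of the copy/progenitor length fraction for
#'   planted cluster members (lower bound >= 0.7).
#' @param tier_fractions per-tier match fractions applied to the
#'   not-yet-matched pool, or NULL when `tier_counts` is given.
#' @param tier_counts exact per-tier match counts (overrides fractions).
#' @param tier_names database names, one per tier.
#' @param n_go_terms integer triple: terms per namespace
#'   (biological_process, molecular_function, cellular_component).
#' @param slim_fraction fraction of terms included in the slim subset
#'   (namespace roots are always included).
#' @param terms_per_contig mean number of direct GO terms per annotated
#'   accession in the generated GAF.
#' @param tissues named integer vector: libraries per tissue.
#' @param n_shared number of transcripts expressed in every tissue.
#' @param n_specific named integer vector: tissue-specific transcript
#'   counts, names matching `tissues`.
#' @param n_transcripts total transcripts in the count matrix; the
#'   remainder beyond expressed ones is silent or near-silent.
#' @param mean_range range of per-transcript expressed means, on the
#'   normalized-count scale (chosen far above the 10/100 filters).
#' @param library_sum_spread max/min ratio of library totals.
#' @param nb_dispersion negative-binomial dispersion (0 = deterministic
#'   integer means).
#' @param n_de number of shared transcripts planted as differentially
#'   expressed (fold change `de_fold_change` in the first tissue).
#' @param de_fold_change fold change applied to planted DE transcripts.
#' @param n_reads number of reads to generate.
#' @param read_length read length in nt.
#' @param adapter adapter sequence planted into contaminated reads.
#' @param contamination_fractions numeric triple, fractions of reads with
#'   (adapter, N-run, low-quality) defects; defects are disjoint.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 1000L,
                       length_median = 700,
                       length_sdlog = 0.75,
                       length_range = c(50L, 7000L),
                       n_short = 0L,
                       cluster_sizes = integer(),
                       substitution_rate = 0.01,
                       member_len_range = c(0.7, 1),
                       tier_fractions = c(0.374, 0.123),
                       tier_counts = NULL,
                       tier_names = c("SwissProt", "TrEMBL"),
                       n_go_terms = c(biological_process = 60L,
                                      molecular_function = 40L,
                                      cellular_component = 25L),
                       slim_fraction = 0.2,
                       terms_per_contig = 4,
                       tissues = c(liver = 3L, gill = 3L),
                       n_shared = 9750L,
                       n_specific = c(liver = 700L, gill = 3378L),
                       n_transcripts = 17951L,
                       mean_range = c(200, 1000),
                       library_sum_spread = 2,
                       nb_dispersion = 0.1,
                       n_de = 0L,
                       de_fold_change = 8,
                       n_reads = 10000L,
                       read_length = 100L,
                       adapter = paste(rep("AGATCGGAAGAGCACACGTC", 4),
                                       collapse = ""),
                       contamination_fractions = c(adapter = 0.1,
                                                   n_run = 0.1,
                                                   low_quality = 0.1)) {
  adapter <- toupper(adapter)
  adapter <- substr(adapter, 1L, 64L)
  cfg <- list(seed = as.integer(seed),
              n_contigs = as.integer(n_contigs),
              length_median = length_median,
              length_sdlog = length_sdlog,
              length_range = as.integer(length_range),
              n_short = as.integer(n_short),
              cluster_sizes = as.integer(cluster_sizes),
              substitution_rate = substitution_rate,
              member_len_range = member_len_range,
              tier_fractions = tier_fractions,
              tier_counts = if (!is.null(tier_counts)) as.integer(tier_counts),
              tier_names = tier_names,
              n_go_terms = as.integer(n_go_terms),
              slim_fraction = slim_fraction,
              terms_per_contig = terms_per_contig,
              tissues = as.integer(tissues) |> setNames(names(tissues)),
              n_shared = as.integer(n_shared),
              n_specific = as.integer(n_specific) |> setNames(names(n_specific)),
              n_transcripts = as.integer(n_transcripts),
              mean_range = mean_range,
              library_sum_spread = library_sum_spread,
              nb_dispersion = nb_dispersion,
              n_de = as.integer(n_de),
              de_fold_change = de_fold_change,
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              adapter = adapter,
              contamination_fractions = contamination_fractions)
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_contigs >= 0L, cfg$n_short >= 0L,
            cfg$length_range[1L] >= 1L,
            cfg$length_range[2L] >= cfg$length_range[1L])
  if (length(cfg$cluster_sizes) && any(cfg$cluster_sizes < 2L))
    stop("planted cluster sizes must all be >= 2", call. = FALSE)
  frac <- c(cfg$substitution_rate, cfg$slim_fraction,
            cfg$contamination_fractions)
  if (any(frac < 0 | frac > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (!is.null(cfg$tier_fractions) &&
      any(cfg$tier_fractions < 0 | cfg$tier_fractions > 1))
    stop("tier_fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$member_len_range[1L] < 0.7 - 1e-12)
    stop("member_len_range lower bound must be >= 0.7", call. = FALSE)
  if (sum(cfg$contamination_fractions) > 1 + 1e-12)
    stop("contamination fractions must sum to <= 1", call. = FALSE)
  total_members <- sum(cfg$cluster_sizes)
  if (total_members > cfg$n_contigs)
    stop("planted cluster membership (", total_members,
         ") exceeds n_contigs (", cfg$n_contigs, ")", call. = FALSE)
  cfg
}

# Fixed per-generator seed offsets (design: one private stream per
# top-level generator call).
.seed_offset <- c(contigs = 101L, tiers = 211L, go = 307L,
                  counts = 401L, reads = 503L)
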