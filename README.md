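# coldref

Post-assembly analysis of a de novo transcriptome, packaged as a set of
composable R functions with a deterministic synthetic-data generator.
The workflow mirrors how a reference transcriptome for a non-model
species (here, an Antarctic notothenioid fish sequenced from pooled
multi-tissue cDNA) is turned into an annotated, expression-profiled
resource:

1. **Contig processing** — drop contigs shorter than 100 nt, then
   collapse redundant contigs: two contigs are linked when they share
   at least 95% nucleotide identity over at least 70% of the shorter
   contig's length (e-value ≤ 1e-9); clusters are single-linkage
   components and only the longest member of each cluster is retained.
2. **Tiered annotation** — screen the retained contigs against ordered
   databases (most specific first); each contig unmatched by earlier
   tiers is queried against the next, and receives the accession of its
   highest-bitscore hit at the e-value cutoff. Hits from the curated
   tiers carry functional annotation; later tiers only count toward the
   expressed-gene tally.
3. **GO assignment and slimming** — map best-hit accessions to Gene
   Ontology terms through a GAF association file, then project direct
   terms onto a GO-slim subset by closest-slim-ancestor (map2slim)
   semantics over the `is_a` DAG.
4. **GO statistics** — compare per-term incidence (number of distinct
   contigs carrying a term) between two transcriptomes with a 2×2
   Pearson chi-square test (X² = N(ad−bc)²/(r₁r₂c₁c₂), no continuity
   correction) or a two-sided Fisher exact test, Benjamini–Hochberg
   corrected; hypergeometric over-representation for gene subsets.
5. **Expression profiling** — clean 100-nt single-end reads (trim
   15 nt head / 6 nt tail; discard on N runs, ≥90% of bases below Q23,
   or any ≥10-nt adapter substring), normalize per-library counts to
   the largest library total (counts × max(sumₖ)/sumₗ), drop
   transcripts with fewer than 10 normalized counts in any library of
   a tissue or ≤100 total, partition expressed transcripts into
   tissue-specific and shared sets, and screen shared transcripts for
   differential expression with a pooled binomial test (pluggable with
   an external moderated-NB result table).

Every generator plants ground truth (cluster partitions, tier
assignments, expressed sets, read defects), so the entire pipeline is
testable end to end without downloading any sequencing data.

## Worked example

```r
library(coldref)

cfg <- sim_config(seed = 42, n_contigs = 500, cluster_sizes = rep(2L, 20),
                  n_transcripts = 800, n_shared = 500,
                  n_specific = c(liver = 40, gill = 90),
                  n_de = 30, de_fold_change = 8, n_reads = 2000)

## redundancy clustering
sim  <- gen_contigs(cfg)
cl   <- build_clusters(pairwise_hits(sim$contigs), sim$contigs)
cl
#> cluster_set: 480 clusters over 500 contigs; 20 multi-member
reps <- select_representatives(cl, sim$contigs)

## tiered annotation + GO
tiers <- gen_reference_tiers(reps, cfg)
ann   <- tiered_annotate(names(reps), tiers$tables, annotation_params())
ann
#> tiered annotation: 217 contigs matched, 263 unmatched
#>   SwissProt       180 /    480  (37.5%)
#>   TrEMBL           37 /    300  (12.3%)
world <- gen_go_world(cfg, accessions = ann$annotation$accession,
                      coverage = 150)
slim  <- map_to_slim(world$graph, world$slim_ids, assign_go(ann, world$goa))
slim
#> contig_go_map: 150 contigs, 547 assignments, 27 distinct terms

## tissue expression profiles
counts <- gen_count_matrix(cfg)
nm     <- normalize_counts(counts$matrix)
part   <- partition_profiles(filter_expression(nm, "liver"),
                             filter_expression(nm, "gill"))
part
#> partition [liver vs gill]: 40 liver-only, 90 gill-only, 500 shared
correlate_shared(part, nm)
#> [1] 0.27
de <- de_shared(part, nm)
sum(counts$truth$de_set %in% de$de_ids)
#> [1] 30

## read cleaning
qc <- clean_reads(gen_reads(cfg)$reads)
qc
#> clean_reads: 2000 in, 1400 retained (70.0%); discarded: n_run=200,
#>   low_quality=200, adapter=200
```

The clustering recovers exactly the 20 planted clusters (480 = 500 −
20 representatives retained), the tier summary reproduces the cascade
accounting (tier 2 is queried only with the 300 contigs tier 1 missed),
the partition recovers the planted tissue sets exactly, and all 30
planted 8-fold-change transcripts are flagged. Note that the pooled
binomial screen also flags many null transcripts under the generator's
biological overdispersion (456 of 500 shared here) — it is a simple
stand-in that is calibrated only for Poisson-level noise; pass
`external =` to `de_shared()` to substitute a moderated-NB result
table for calibrated calls (see the methods vignette).

A command-line front end with `simulate`, `clean-reads`, `cluster`,
`annotate`, `compare-go`, `profile` and `run` subcommands is installed
at `inst/scripts/coldref`; `run_pipeline()` executes configured stages
and writes a JSON manifest with every applied parameter and per-stage
record counts.

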