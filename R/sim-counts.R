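#' Generate a tissue count matrix with planted expression classes
#'
#' Transcripts fall into planted classes: `n_shared` expressed in every
#' tissue, `n_specific[t]` expressed only in tissue t (zero counts
#' elsewhere), and the remainder up to `n_transcripts` silent — half
#' with all-zero counts, half near-silent (negative-binomial mean 2 per
#' library, far below the expression filters).  Expressed transcripts
#' draw a per-transcript integer base mean on `mean_range`, chosen so
#' that, after library-size normalization, they clear the >=10
#' per-library and >100 total filters; counts are negative-binomial
#' with dispersion `nb_dispersion` (0 gives counts exactly equal to
#' their integer means).  Library depths are geometrically spaced so
#' raw library totals span `library_sum_spread`.  `n_de` shared
#' transcripts get a `de_fold_change`-fold mean in the first tissue.
#'
#' @param cfg a [sim_config()].
#' @return A list with `matrix` (a raw [count_matrix()]) and `truth`
#'   (list with `expressed_sets` per tissue, `de_set`, `silent`).
#' @export
gen_count_matrix <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  tissues <- cfg$tissues
  if (length(tissues) < 2L || any(tissues < 1L))
    stop("need at least two tissues with one library each", call. = FALSE)
  if (is.null(names(tissues)) || !all(names(cfg$n_specific) %in% names(tissues)))
    stop("n_specific names must match tissue names", call. = FALSE)
  n_spec <- setNames(rep(0L, length(tissues)), names(tissues))
  n_spec[names(cfg$n_specific)] <- cfg$n_specific
  n_expr <- cfg$n_shared + sum(n_spec)
  if (cfg$n_transcripts < n_expr)
    stop("n_transcripts smaller than planted expressed transcripts",
         call. = FALSE)
  with_seed(cfg$seed + .seed_offset[["counts"]], {
    n_silent <- cfg$n_transcripts - n_expr
    ids <- sprintf("transcript%06d", seq_len(cfg$n_transcripts))
    perm <- sample(ids)
    shared <- perm[seq_len(cfg$n_shared)]
    off <- cfg$n_shared
    specific <- list()
    for (t in names(tissues)) {
      specific[[t]] <- if (n_spec[[t]] > 0L)
        perm[off + seq_len(n_spec[[t]])] else character()
      off <- off + n_spec[[t]]
    }
    silent <- perm[off + seq_len2(n_silent)]
    near_silent <- silent[seq_len2(n_silent %/% 2L)]

    libs <- unlist(lapply(names(tissues), function(t)
      paste0(t, sprintf("%02d", seq_len(tissues[[t]])))), use.names = FALSE)
    lib_tissue <- rep(names(tissues), tissues)
    L <- length(libs)
    depth <- if (L == 1L) 1 else
      cfg$library_sum_spread^(-(sample(L) - 1) / (L - 1))

    base_mean <- setNames(numeric(cfg$n_transcripts), ids)
    base_mean[shared] <- sample(cfg$mean_range[1L]:cfg$mean_range[2L],
                                cfg$n_shared, replace = TRUE)
    for (t in names(tissues))
      base_mean[specific[[t]]] <-
        sample(cfg$mean_range[1L]:cfg$mean_range[2L], n_spec[[t]],
               replace = TRUE)
    base_mean[near_silent] <- 2

    de_set <- character()
    if (cfg$n_de > 0L) {
      de_set <- sample(shared, min(cfg$n_de, length(shared)))
    }

    counts <- matrix(0, nrow = cfg$n_transcripts, ncol = L,
                     dimnames = list(ids, libs))
    for (l in seq_len(L)) {
      t <- lib_tissue[l]
      active <- c(shared, specific[[t]], near_silent)
      mu <- base_mean[active] * depth[l]
      if (t == names(tissues)[1L] && length(de_set))
        mu[match(de_set, active)] <- mu[match(de_set, active)] *
          cfg$de_fold_change
      draw <- if (cfg$nb_dispersion > 0)
        rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      else round(mu)
      # keep planted truth exact under the expression filters for any
      # seed: expressed transcripts are floored safely above the
      # normalized-count thresholds, near-silent ones capped below the
      # per-library floor (both bounds are far into the NB tails, so
      # they essentially never bind)
      expressed_here <- active %in% c(shared, specific[[t]])
      floor_raw <- as.integer(ceiling(50 * depth[l]))
      cap_raw <- as.integer(floor(9 * depth[l]))
      draw[expressed_here] <- pmax(draw[expressed_here], floor_raw)
      draw[!expressed_here] <- pmin(draw[!expressed_here], cap_raw)
      counts[active, l] <- draw
    }
    expressed <- lapply(names(tissues), function(t)
      sort(c(shared, specific[[t]])))
    names(expressed) <- names(tissues)
    list(matrix = count_matrix(counts, lib_tissue, state = "raw"),
         truth = list(expressed_sets = expressed,
                      shared = sort(shared),
                      specific = lapply(specific, sort),
                      de_set = sort(de_set),
                      silent = sort(silent)))
  })
}

# seq_len that tolerates 0 without surprises in slicing helpers
seq_len2 <- function(n) if (n > 0L) seq_len(n) else integer()
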