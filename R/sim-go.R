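#' Generate a synthetic GO world: DAG, slim subset and accession mapping
#'
#' Builds one rooted DAG per namespace (is_a edges only): terms are
#' added in sequence, each drawing one or two parents among earlier
#' terms of its namespace (so every term reaches its namespace root and
#' the graph is acyclic by construction).  The slim subset contains
#' every namespace root plus a `slim_fraction` sample of the remaining
#' terms.  Accessions receive leaf-biased direct terms: sampling
#' weights double for terms without children.
#'
#' Exact per-namespace assignment totals can be requested with
#' `assignment_totals`; otherwise each accession draws about
#' `terms_per_contig` terms overall.
#'
#' @param cfg a [sim_config()].
#' @param accessions accessions to annotate; default synthetic ones
#'   (`ACC000001`, ...) for `n_contigs` entries.
#' @param coverage number of accessions (from the start of the list)
#'   that appear in the GAF; defaults to all.
#' @param assignment_totals optional named integer triple
#'   (biological_process, molecular_function, cellular_component):
#'   exact number of (accession, term) assignments per namespace,
#'   spread evenly (+/-1) over covered accessions.
#' @return A list with `graph` (a [go_graph()]), `slim_ids`, `goa`
#'   (data.frame accession/go_id/aspect) and `truth` (list with
#'   `terms_of_accession`).
#' @export
gen_go_world <- function(cfg, accessions = NULL, coverage = NULL,
                         assignment_totals = NULL) {
  cfg <- validate_sim_config(cfg)
  stopifnot(all(cfg$n_go_terms >= 1L))
  with_seed(cfg$seed + .seed_offset[["go"]], {
    spaces <- c("biological_process", "molecular_function",
                "cellular_component")
    aspect_of <- c(biological_process = "P", molecular_function = "F",
                   cellular_component = "C")
    n_terms <- setNames(rep_len(cfg$n_go_terms, 3L), spaces)

    ids <- character(); names_ <- character(); namespace <- character()
    parents <- list()
    k <- 0L
    for (s in spaces) {
      local_ids <- sprintf("GO:%07d", k + seq_len(n_terms[[s]]))
      k <- k + n_terms[[s]]
      ids <- c(ids, local_ids)
      names_ <- c(names_, paste0(s, " term ", seq_len(n_terms[[s]])))
      namespace <- c(namespace, rep(s, n_terms[[s]]))
      for (i in seq_len(n_terms[[s]])) {
        parents[[local_ids[i]]] <- if (i == 1L) character() else {
          np <- if (i > 2L && runif(1) < 0.3) 2L else 1L
          sample(local_ids[seq_len(i - 1L)], min(np, i - 1L))
        }
      }
    }
    terms <- data.frame(id = ids, name = names_, namespace = namespace,
                        stringsAsFactors = FALSE)
    graph <- go_graph(terms, parents)

    roots <- unname(graph$roots)
    non_roots <- setdiff(ids, roots)
    n_slim <- round(cfg$slim_fraction * length(non_roots))
    slim_ids <- sort(c(roots, if (n_slim > 0) sample(non_roots, n_slim)))

    if (is.null(accessions))
      accessions <- sprintf("ACC%06d", seq_len(cfg$n_contigs))
    coverage <- coverage %||% length(accessions)
    covered <- accessions[seq_len(min(coverage, length(accessions)))]

    has_child <- ids %in% unlist(parents, use.names = FALSE)
    weight_of <- function(s) {
      w <- ifelse(has_child[namespace == s], 1, 2)
      setNames(w, ids[namespace == s])
    }

    goa_rows <- vector("list", 3L); names(goa_rows) <- spaces
    for (s in spaces) {
      w <- weight_of(s)
      pool <- names(w)
      if (!is.null(assignment_totals)) {
        total <- assignment_totals[[s]]
        base <- total %/% length(covered)
        extra <- total %% length(covered)
        n_per <- rep(base, length(covered))
        if (extra > 0) {
          idx <- sample.int(length(covered), extra)
          n_per[idx] <- n_per[idx] + 1L
        }
      } else {
        lam <- cfg$terms_per_contig / 3
        n_per <- pmax(if (s == spaces[1L]) 1L else 0L,
                      stats::rpois(length(covered), lam))
      }
      n_per <- pmin(n_per, length(pool))
      tot <- sum(n_per)
      acc_rep <- rep(covered, n_per)
      term_draw <- unlist(lapply(n_per, function(m)
        if (m > 0L) sample(pool, m, prob = w) else character()),
        use.names = FALSE)
      goa_rows[[s]] <- data.frame(accession = acc_rep, go_id = term_draw,
                                  aspect = aspect_of[[s]],
                                  stringsAsFactors = FALSE)
    }
    goa <- do.call(rbind, c(goa_rows, list(make.row.names = FALSE)))
    list(graph = graph, slim_ids = slim_ids, goa = goa,
         truth = list(terms_of_accession = goa_as_map(goa)))
  })
}
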