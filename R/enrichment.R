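#' Over-representation analysis of a metabolite set
#'
#' For each pathway (intersected with the measured universe first), tests
#' whether the query contains more pathway members than expected for a
#' random same-size query: exact hypergeometric upper-tail
#' `P(X >= k)` and an empirical permutation P-value
#' `(1 + #{random queries with hits >= k}) / (1 + n_permutations)` from
#' uniformly drawn same-size subsets of the universe (the two agree as the
#' permutation count grows). Pathways with no member in the universe are
#' skipped with a warning.
#'
#' @param query Character vector of selected metabolites (subset of
#'   `universe`).
#' @param universe Character vector of all measured metabolites (after
#'   exclusions).
#' @param pathway_sets List of `pathway_set` objects (or a named list of
#'   member vectors).
#' @param n_permutations Random queries for the permutation null (>= 1).
#' @param seed Seed for the permutation draw.
#' @return Data frame sorted by permutation P: pathway, universe / pathway /
#'   query sizes, hits, both P-values and the enrichment ratio
#'   `k / (n M / N)`.
#' @export
enrichment_ora <- function(query, universe, pathway_sets,
                           n_permutations = 1000L, seed = 1L) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  stopifnot(n_permutations >= 1)
  sets <- as_pathway_sets(pathway_sets)
  N <- length(universe)
  nq <- length(query)
  mem <- lapply(sets, function(s) intersect(s$members, universe))
  sizes <- lengths(mem)
  empty <- sizes == 0
  if (any(empty)) {
    warning("skipping pathway(s) with no member in the universe: ",
            paste(vapply(sets[empty], `[[`, "", "name"), collapse = ", "))
    sets <- sets[!empty]
    mem <- mem[!empty]
    sizes <- sizes[!empty]
  }
  if (length(sets) == 0)
    return(data.frame(pathway = character(0), universe_size = integer(0),
                      pathway_size = integer(0), query_size = integer(0),
                      hits = integer(0), p_hypergeometric = numeric(0),
                      p_permutation = numeric(0),
                      enrichment_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  k <- vapply(mem, function(m) length(intersect(query, m)), integer(1))
  p_hyper <- stats::phyper(k - 1, sizes, N - sizes, nq, lower.tail = FALSE)
  memb <- vapply(mem, function(m) universe %in% m,
                 logical(N))  # N x S indicator
  cnt <- numeric(length(sets))
  set.seed(stage_seed(seed, "ora_permutations"))
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(N, nq)
    hits <- colSums(memb[idx, , drop = FALSE])
    cnt <- cnt + (hits >= k)
  }
  out <- data.frame(pathway = vapply(sets, `[[`, "", "name"),
                    universe_size = N, pathway_size = sizes,
                    query_size = nq, hits = k,
                    p_hypergeometric = p_hyper,
                    p_permutation = (1 + cnt) / (1 + n_permutations),
                    enrichment_ratio = k / (nq * sizes / N),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_permutation, out$p_hypergeometric), ]
  rownames(out) <- NULL
  out
}

#' Per-component enrichment joined with age behavior
#'
#' Runs [enrichment_ora()] on the final metabolites assigned to each
#' principal component (against the full measured universe) and joins each
#' component's top-ranked pathway with the component's age classification
#' into a headline table (pathway by age behavior).
#'
#' @param selection A `selection_result` from [select_metabolites()], or a
#'   data frame like [step4_intersect()]'s output.
#' @param profiles A `component_age_profile` from [component_age_screen()].
#' @param pathway_sets Pathway definitions (see [enrichment_ora()]).
#' @param universe All measured metabolites after exclusions.
#' @param config A [run_config()] (uses `n_permutations`, floored at 1000
#'   draws for stable P-values).
#' @param seed Seed.
#' @return List with `per_component` (one enrichment table per component)
#'   and the `headline` data frame.
#' @export
per_component_enrichment <- function(selection, profiles, pathway_sets,
                                     universe, config = run_config(),
                                     seed = config$seed) {
  final <- if (inherits(selection, "selection_result")) selection$final
    else selection
  comps <- profiles$component
  n_perm <- max(config$n_permutations, 1000L)
  per_comp <- list()
  headline <- list()
  for (cn in comps) {
    q <- final$metabolite[final$component == cn]
    if (length(q) == 0) {
      per_comp[[cn]] <- data.frame()
      next
    }
    res <- enrichment_ora(q, universe, pathway_sets,
                          n_permutations = n_perm,
                          seed = stage_seed(seed, paste0("enrich_", cn)))
    per_comp[[cn]] <- res
    if (nrow(res)) {
      headline[[cn]] <- data.frame(
        component = cn,
        classification = profiles$classification[profiles$component == cn],
        top_pathway = res$pathway[1],
        hits = res$hits[1],
        p_permutation = res$p_permutation[1],
        p_hypergeometric = res$p_hypergeometric[1],
        stringsAsFactors = FALSE)
    }
  }
  headline <- if (length(headline)) do.call(rbind, headline) else
    data.frame(component = character(0), classification = character(0),
               top_pathway = character(0), hits = integer(0),
               p_permutation = numeric(0), p_hypergeometric = numeric(0),
               stringsAsFactors = FALSE)
  rownames(headline) <- NULL
  list(per_component = per_comp, headline = headline)
}
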