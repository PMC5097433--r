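#' Propagate annotations up an is_a ontology (true-path rule)
#'
#' Annotates every gene to all ancestors of each of its direct terms, so a
#' gene annotated to "aggregation" also counts for "development" and the
#' root. Idempotent; terms absent from the edge list are kept as isolated
#' terms.
#'
#' @param ontology_edges tibble `child_term`, `parent_term` (is_a edges).
#' @param annotations tibble `gene_id`, `term_id` (direct annotations).
#' @return tibble `gene_id`, `term_id`, upward-closed and de-duplicated.
#' @export
propagate_annotations <- function(ontology_edges, annotations) {
  terms <- unique(c(ontology_edges$child_term, ontology_edges$parent_term,
                    annotations$term_id))
  g <- igraph::graph_from_data_frame(
    ontology_edges[, c("child_term", "parent_term")],
    directed = TRUE, vertices = data.frame(name = terms)
  )
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    stop("ontology contains a cycle involving terms: ",
         paste(unique(as.vector(ends)), collapse = ", "), call. = FALSE)
  }
  anc <- lapply(setNames(terms, terms), function(t) {
    names(igraph::subcomponent(g, t, mode = "out"))
  })
  annotations |>
    dplyr::distinct(.data$gene_id, .data$term_id) |>
    dplyr::mutate(term_id = anc[.data$term_id]) |>
    tidyr::unnest("term_id") |>
    dplyr::distinct(.data$gene_id, .data$term_id) |>
    dplyr::arrange(.data$gene_id, .data$term_id)
}

#' Hypergeometric term enrichment over a study set
#'
#' For each annotated term, tests whether the study set contains more
#' annotated genes than expected under sampling without replacement from
#' the population: upper-tail hypergeometric
#' `p = P(X >= k_study | n_pop, k_pop, n_study)`, Benjamini-Hochberg
#' adjusted across the tested terms. Terms with fewer than
#' `min_study_genes` study annotations are not reported (noise
#' suppression).
#'
#' @param study character vector of gene ids, a subset of `population`.
#' @param population character vector of background gene ids (typically all
#'   genes with at least one propagated annotation).
#' @param annotations propagated annotation tibble `gene_id`, `term_id`.
#' @param fdr reporting FDR (kept on the result; no rows are removed by q).
#' @param min_study_genes minimum study-annotation count for a term to be
#'   tested (default 2).
#' @return tibble sorted by `q_value`: `term_id`, `k_study`, `n_study`,
#'   `k_pop`, `n_pop`, `p_value`, `q_value`, `enriched`.
#' @export
hypergeometric_enrichment <- function(study, population, annotations,
                                      fdr = 0.10, min_study_genes = 2) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population))
    stop("study set is not a subset of the population", call. = FALSE)
  ann <- annotations |>
    dplyr::filter(.data$gene_id %in% population) |>
    dplyr::distinct(.data$gene_id, .data$term_id)
  n_pop <- length(population)
  n_study <- length(study)
  per_term <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      k_pop = dplyr::n_distinct(.data$gene_id),
      k_study = dplyr::n_distinct(.data$gene_id[.data$gene_id %in% study]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k_study >= min_study_genes)
  if (nrow(per_term) == 0) {
    return(tibble::tibble(term_id = character(), k_study = integer(),
                          n_study = integer(), k_pop = integer(),
                          n_pop = integer(), p_value = double(),
                          q_value = double(), enriched = logical()))
  }
  p <- phyper(per_term$k_study - 1, per_term$k_pop,
              n_pop - per_term$k_pop, n_study, lower.tail = FALSE)
  out <- per_term |>
    dplyr::mutate(n_study = n_study, n_pop = n_pop, p_value = p,
                  q_value = bh_adjust(p)) |>
    dplyr::mutate(enriched = .data$q_value <= fdr) |>
    dplyr::select("term_id", "k_study", "n_study", "k_pop", "n_pop",
                  "p_value", "q_value", "enriched") |>
    dplyr::arrange(.data$q_value, .data$p_value, .data$term_id)
  out
}
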