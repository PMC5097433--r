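#' Synthetic gene ontology and annotations
#'
#' `sim_ontology()` returns a small fixed is_a DAG (a root biological-process
#' term, three branch terms and eight leaf terms, including one diamond) used
#' by the synthetic annotation generator. `simulate_annotations()` assigns
#' leaf terms to genes: every gene draws one or two random leaves with
#' probability 0.9, and planted core-developmental genes additionally draw a
#' development leaf with probability 0.8, so development terms come out
#' enriched in the planted core set.
#'
#' @return `sim_ontology()`: tibble with columns `child_term`, `parent_term`.
#' @examples
#' sim_ontology()
#' @export
sim_ontology <- function() {
  tibble::tribble(
    ~child_term,   ~parent_term,
    "GO:9110000", "GO:9100000", # development is_a biological_process
    "GO:9120000", "GO:9100000", # signaling
    "GO:9130000", "GO:9100000", # metabolism
    "GO:9110001", "GO:9110000", # aggregation
    "GO:9110002", "GO:9110000", # mound formation
    "GO:9110003", "GO:9110000", # culmination
    "GO:9110004", "GO:9110002", # sporulation (diamond: two parents)
    "GO:9110004", "GO:9110003",
    "GO:9120001", "GO:9120000", # cAMP signaling
    "GO:9120002", "GO:9120000", # kinase cascade
    "GO:9130001", "GO:9130000", # carbohydrate metabolism
    "GO:9130002", "GO:9130000"  # amino-acid metabolism
  )
}

#' @rdname sim_ontology
#' @param catalogue gene catalogue from [simulate_families()].
#' @param config the [sim_config()]; only the seed is used (annotation
#'   stream is derived as `seed + 2`).
#' @param p_annotated probability that a gene carries any annotation.
#' @param p_core_dev_term probability that a planted core gene carries an
#'   extra development leaf term.
#' @return `simulate_annotations()`: tibble with columns `gene_id`,
#'   `term_id` (direct, unpropagated annotations).
#' @export
simulate_annotations <- function(catalogue, config,
                                 p_annotated = 0.9,
                                 p_core_dev_term = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  onto <- sim_ontology()
  leaves <- setdiff(onto$child_term, onto$parent_term)
  dev_leaves <- c("GO:9110001", "GO:9110002", "GO:9110003", "GO:9110004")
  cat_sorted <- dplyr::arrange(catalogue, .data$species, .data$gene_id)
  rows <- vector("list", nrow(cat_sorted))
  for (i in seq_len(nrow(cat_sorted))) {
    terms <- character(0)
    if (runif(1) < p_annotated) {
      terms <- sample(leaves, sample(1:2, 1))
    }
    if (isTRUE(cat_sorted$truth_core_dev[i]) && runif(1) < p_core_dev_term) {
      terms <- union(terms, sample(dev_leaves, 1))
    }
    if (length(terms) > 0) {
      rows[[i]] <- tibble::tibble(gene_id = cat_sorted$gene_id[i],
                                  term_id = sort(terms))
    }
  }
  dplyr::bind_rows(rows)
}
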