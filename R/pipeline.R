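#' Run the full core-set pipeline on one data set
#'
#' Chains every stage: protein similarity graph and Markov clustering into
#' ortholog families; per-species rpkm profiles; the three up-regulation
#' callers (Method A threshold, Method B species-as-replicates, Method C
#' strain-as-replicates); DD anchoring and the Venn core set; optional GO
#' enrichment of the core against the annotated background; and the
#' DD-DF conservation-vs-peak-stage analysis over the union of the three
#' sets. The pipeline itself consumes no randomness, so identical inputs
#' give identical outputs.
#'
#' @param catalogue gene catalogue tibble (`gene_id`, `species`,
#'   `cds_length_nt`, `protein`).
#' @param counts named list of count tibbles; needs `DD`, `DL`, `PP`, `DF`
#'   and (for Method C) `AX4`.
#' @param annotations optional direct annotation tibble (`gene_id`,
#'   `term_id`).
#' @param ontology_edges optional is_a edge tibble.
#' @param min_weight,inflation similarity-graph / MCL parameters.
#' @param min_reads,min_fold,min_similarity,min_species Method A parameters.
#' @param fdr FDR for Methods B and C.
#' @return list of class `core_pipeline`: `families` (ortholog_families),
#'   `family_stats`, `profiles`, `method_a`, `method_b`, `method_c`,
#'   `report` (core_report), `enrichment` (or NULL), `conservation`
#'   (records tibble) and `conservation_test` (or NULL when a peak group is
#'   empty).
#' @export
run_core_pipeline <- function(catalogue, counts,
                              annotations = NULL, ontology_edges = NULL,
                              min_weight = 0.25, inflation = 2,
                              min_reads = 20, min_fold = 3,
                              min_similarity = 0.5, min_species = 3,
                              fdr = 0.10) {
  edges <- similarity_graph(catalogue, min_weight = min_weight)
  fams <- mcl_cluster(edges, catalogue = catalogue, inflation = inflation)
  stats <- family_stats(fams$families)

  ma <- method_a(counts, catalogue, fams$families,
                 min_reads = min_reads, min_fold = min_fold,
                 min_similarity = min_similarity, min_species = min_species)
  mb <- method_b(counts, fams$families, fdr = fdr)
  mc_ <- method_c(counts$DD, counts$AX4, fdr = fdr)

  set_a <- ma$dd_anchored_set
  set_b <- anchor_to_dd(mb$called, fams$families, method = "family")
  # Method C: keep only genes with an ortholog in some other species
  dd_in_fam <- fams$families |>
    dplyr::group_by(.data$family_id) |>
    dplyr::filter(dplyr::n_distinct(.data$species) >= 2) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$species == "DD") |>
    dplyr::pull(.data$gene_id)
  set_c <- intersect(anchor_to_dd(mc_$called, fams$families, method = "gene"),
                     dd_in_fam)
  report <- venn_partition(set_a, set_b, set_c)

  enr <- NULL
  if (!is.null(annotations) && !is.null(ontology_edges) &&
      length(report$core) > 0) {
    prop <- propagate_annotations(ontology_edges, annotations)
    dd_genes <- catalogue$gene_id[catalogue$species == "DD"]
    population <- intersect(unique(prop$gene_id), dd_genes)
    study <- intersect(report$core, population)
    if (length(study) > 0) {
      enr <- hypergeometric_enrichment(study, population, prop, fdr = fdr)
    }
  }

  defined_set <- sort(unique(c(set_a, set_b, set_c)))
  cons <- conservation_records(defined_set, fams$families, catalogue,
                               ma$profiles$DD)
  cons_test <- NULL
  if (any(cons$peak_stage %in% c("t3", "t4")) &&
      any(cons$peak_stage == "t1")) {
    cons_test <- conservation_by_peak(cons)
  }

  structure(
    list(families = fams, family_stats = stats, profiles = ma$profiles,
         method_a = ma, method_b = mb, method_c = mc_,
         sets = list(A = set_a, B = set_b, C = set_c),
         report = report, enrichment = enr,
         conservation = cons, conservation_test = cons_test),
    class = "core_pipeline"
  )
}

#' @export
print.core_pipeline <- function(x, ...) {
  cat("<core_pipeline>\n")
  cat(sprintf("  families (>=2 members): %d\n",
              x$family_stats$n_families_ge2))
  cat(sprintf("  method A/B/C DD-anchored: %d / %d / %d\n",
              length(x$sets$A), length(x$sets$B), length(x$sets$C)))
  cat(sprintf("  union %d, core (A&B&C) %d\n", x$report$union_size,
              length(x$report$core)))
  if (!is.null(x$conservation_test))
    cat(sprintf("  conservation late vs early: one-sided p = %.4g\n",
                x$conservation_test$p_value))
  invisible(x)
}

#' Write the pipeline report to plain-text files
#'
#' Serialises the result of [run_core_pipeline()]: families TSV, per-method
#' DD-anchored set TSVs, profile TSVs, the Venn/core JSON, the core gene
#' TSV and the conservation TSV. Output is deterministic, so two runs on
#' the same inputs produce byte-identical files.
#'
#' @param pipeline a `core_pipeline`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_core_report <- function(pipeline, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create ", out_dir, call. = FALSE)
  files <- character(0)
  w <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    files <<- c(files, path)
  }
  w(pipeline$families$families, "families.tsv")
  for (m in c("A", "B", "C")) {
    w(tibble::tibble(gene_id = pipeline$sets[[m]]),
      sprintf("set_%s.tsv", tolower(m)))
  }
  w(tibble::tibble(gene_id = pipeline$report$core), "core_genes.tsv")
  w(pipeline$conservation, "conservation.tsv")
  for (sp in names(pipeline$profiles)) {
    w(pipeline$profiles[[sp]], sprintf("profiles_%s.tsv", sp))
  }
  json_path <- file.path(out_dir, "coreset.json")
  jsonlite::write_json(
    list(venn_counts = as.list(pipeline$report$venn_counts),
         union_size = pipeline$report$union_size,
         core = pipeline$report$core),
    json_path, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, json_path)
  invisible(files)
}
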