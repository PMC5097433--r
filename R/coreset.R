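#' Map called units to a DD-anchored gene set
#'
#' Method B units are family ids: each maps to its unique D. discoideum
#' member (families without a DD member are dropped, with a message).
#' Method C units are already DD gene ids and pass through.
#'
#' @param units character vector of called unit ids.
#' @param families tibble `family_id`, `gene_id`, `species`.
#' @param method `"family"` (Method B) or `"gene"` (Method C).
#' @return character vector of DD gene ids.
#' @export
anchor_to_dd <- function(units, families, method = c("family", "gene")) {
  method <- match.arg(method)
  if (method == "gene") return(sort(unique(units)))
  dd <- families |>
    dplyr::filter(.data$family_id %in% units, .data$species == "DD")
  dup <- dd |> dplyr::count(.data$family_id) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    stop("family with more than one DD member among called units: ",
         paste(head(dup$family_id, 3), collapse = ", "), call. = FALSE)
  n_dropped <- length(setdiff(units, dd$family_id))
  if (n_dropped > 0)
    message(n_dropped, " called unit(s) without a DD member dropped")
  sort(unique(dd$gene_id))
}

VENN_REGIONS <- c("A_only", "B_only", "C_only", "AB_only", "AC_only",
                  "BC_only", "ABC")

#' Venn partition of the three method sets and the core set
#'
#' Exact set algebra over the DD-anchored gene sets of the three callers:
#' the seven exclusive Venn regions, the union, and the core set (the
#' triple intersection). All seven regions are reported even when empty.
#'
#' @param set_a,set_b,set_c character vectors of DD gene ids.
#' @return object of class `core_report`: `sets` (the three input sets),
#'   `venn_counts` (named integer, regions `A_only` ... `ABC`),
#'   `union_size`, `core` (character vector, = A intersect B intersect C).
#' @export
venn_partition <- function(set_a, set_b, set_c) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  counts <- c(
    A_only = sum(ina & !inb & !inc),
    B_only = sum(!ina & inb & !inc),
    C_only = sum(!ina & !inb & inc),
    AB_only = sum(ina & inb & !inc),
    AC_only = sum(ina & !inb & inc),
    BC_only = sum(!ina & inb & inc),
    ABC = sum(ina & inb & inc)
  )
  structure(
    list(sets = list(A = sort(a), B = sort(b), C = sort(c)),
         venn_counts = counts,
         union_size = length(u),
         core = sort(u[ina & inb & inc])),
    class = "core_report"
  )
}

#' @export
print.core_report <- function(x, ...) {
  cat("<core_report>\n")
  for (r in VENN_REGIONS) cat(sprintf("  %-8s %d\n", r, x$venn_counts[[r]]))
  cat(sprintf("  union    %d\n  core     %d\n", x$union_size,
              length(x$core)))
  invisible(x)
}

#' Overlap of a mutant phenotype catalogue with the ortholog set
#'
#' Given a catalogue of DD genes whose disruption gives a developmental
#' phenotype, counts how many have an ortholog family with at least one
#' member in every other species, the same fraction over all DD genes as a
#' genome baseline, and the intersection with the developmentally
#' up-regulated set. Percentages are `100 * k / n` rounded half-up to whole
#' percent (see [overlap_percentage()]).
#'
#' @param catalogue_genes character vector of DD gene ids with phenotypes.
#' @param dd_upregulated character vector of DD-anchored up-regulated genes.
#' @param families tibble `family_id`, `gene_id`, `species`.
#' @param n_all_dd total number of DD genes in the genome.
#' @return one-row tibble: `n_catalogue`, `n_with_orthologs_all`,
#'   `pct_with_orthologs_all`, `n_all_genes`, `n_genes_ortholog_all`,
#'   `pct_genome_baseline`, `n_dev_upregulated_in_catalogue`.
#' @export
mutant_overlap <- function(catalogue_genes, dd_upregulated, families,
                           n_all_dd) {
  others <- setdiff(SPECIES, "DD")
  fam_all <- families |>
    dplyr::filter(.data$species %in% others) |>
    dplyr::distinct(.data$family_id, .data$species) |>
    dplyr::count(.data$family_id) |>
    dplyr::filter(.data$n == length(others)) |>
    dplyr::pull(.data$family_id)
  dd_with_all <- families |>
    dplyr::filter(.data$species == "DD", .data$family_id %in% fam_all) |>
    dplyr::pull(.data$gene_id) |>
    unique()
  n_cat <- length(unique(catalogue_genes))
  k_cat <- length(intersect(unique(catalogue_genes), dd_with_all))
  k_all <- length(dd_with_all)
  tibble::tibble(
    n_catalogue = n_cat,
    n_with_orthologs_all = k_cat,
    pct_with_orthologs_all = overlap_percentage(k_cat, n_cat),
    n_all_genes = as.integer(n_all_dd),
    n_genes_ortholog_all = k_all,
    pct_genome_baseline = overlap_percentage(k_all, n_all_dd),
    n_dev_upregulated_in_catalogue =
      length(intersect(unique(catalogue_genes), dd_upregulated))
  )
}

#' Simulate a mutant phenotype catalogue
#'
#' Draws a synthetic stand-in for a curated catalogue of genes with
#' developmental phenotypes: a fraction of the planted core-developmental
#' DD genes plus random non-core DD genes as noise, so that
#' [mutant_overlap()] is exercisable without any external database.
#'
#' @param catalogue gene catalogue from [simulate_families()].
#' @param truth truth list from [simulate_families()].
#' @param frac_core fraction of planted core DD genes included.
#' @param frac_noise fraction of the remaining DD genes included.
#' @param seed integer seed.
#' @return character vector of DD gene ids.
#' @export
simulate_mutant_catalogue <- function(catalogue, truth, frac_core = 0.6,
                                      frac_noise = 0.05, seed = 1L) {
  set.seed(seed)
  dd <- catalogue |> dplyr::filter(.data$species == "DD")
  core <- dd$gene_id[dd$truth_core_dev]
  rest <- setdiff(dd$gene_id, core)
  picked_core <- sample(core, round_half_up(frac_core * length(core)))
  picked_noise <- sample(rest, round_half_up(frac_noise * length(rest)))
  sort(c(picked_core, picked_noise))
}
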