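# Shared fixture builders. Everything is generated in code at test time.

# a small catalogue built by hand: n one-per-species families, optionally
# planted with a fold change at a peak stage
toy_catalogue <- function(n_fam = 20, planted = integer(0), fold = 10,
                          peak = "t3", len_nt = 600, species = c("DD", "DL", "PP", "DF")) {
  rows <- list()
  prot <- paste(rep("ACDEFGHIKL", len_nt / 30), collapse = "")
  for (i in seq_len(n_fam)) {
    for (sp in species) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = sprintf("%s_F%03d", sp, i),
        species = sp,
        cds_length_nt = as.integer(len_nt),
        protein = prot,
        truth_family = sprintf("F%03d", i),
        truth_core_dev = i %in% planted,
        truth_peak_stage = if (i %in% planted) peak else NA_character_,
        truth_fold = if (i %in% planted) fold else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

truth_of <- function(catalogue) {
  planted <- catalogue[!is.na(catalogue$truth_peak_stage), ]
  sp_list <- lapply(stats::setNames(unique(catalogue$species),
                                    unique(catalogue$species)),
                    function(sp) planted$gene_id[planted$species == sp])
  list(
    core_dev_families = sort(unique(stats::na.omit(
      catalogue$truth_family[catalogue$truth_core_dev]))),
    per_species_upregulated = sp_list,
    peak_stage = stats::setNames(planted$truth_peak_stage, planted$gene_id)
  )
}

# families tibble straight from simulation truth (bypasses clustering)
truth_families <- function(catalogue) {
  catalogue |>
    dplyr::filter(!is.na(.data$truth_family)) |>
    dplyr::transmute(family_id = .data$truth_family, .data$gene_id,
                     .data$species)
}

# a count tibble with explicit per-stage counts
toy_counts <- function(gene_ids, mat) {
  stopifnot(ncol(mat) == 5)
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  names(out) <- c("t0", "t1", "t2", "t3", "t4")
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), out)
}

# short-protein config for sequence-heavy simulations in tests
fast_cfg <- function(seed, ...) {
  sim_config(seed = seed, cds_length_range = c(300, 900), ...)
}
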