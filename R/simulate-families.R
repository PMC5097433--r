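#' Simulate four-species gene catalogues with planted ground truth
#'
#' Draws an ancestral protein per conserved family and evolves it along the
#' fixed species topology `((DF,PP),(DL,DD))` with Poisson-sampled amino-acid
#' substitutions at a peak-stage-dependent rate (late-peaking families evolve
#' more slowly, encoding the conservation gradient), per-branch duplication
#' and loss, plus species-specific singleton genes. A fraction
#' `frac_core_dev` of conserved families is planted as developmentally
#' up-regulated in all four species.
#'
#' All branches have length 1; divergence is controlled entirely by the
#' per-family substitution rate. Substitutions replace a site by one of the
#' 19 other residues, drawn uniformly.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{catalogue}{tibble with one row per gene: `gene_id`, `species`,
#'       `cds_length_nt`, `protein`, and the simulation truth columns
#'       `truth_family`, `truth_core_dev`, `truth_peak_stage`, `truth_fold`
#'       (all `NA` for non-planted genes).}
#'     \item{truth}{list with `core_dev_families` (family ids),
#'       `per_species_upregulated` (named list species -> gene ids) and
#'       `peak_stage` (named character, gene id -> stage).}
#'   }
#' @examples
#' sim <- simulate_families(sim_config(seed = 7, n_families_conserved = 10))
#' dplyr::count(sim$catalogue, species)
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  n_fam <- config$n_families_conserved
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  n_core <- round_half_up(config$frac_core_dev * n_fam)
  core_idx <- if (n_core > 0) sort(sample.int(n_fam, n_core)) else integer(0)
  is_core <- seq_len(n_fam) %in% core_idx

  peak <- rep(NA_character_, n_fam)
  fold <- rep(NA_real_, n_fam)
  if (n_core > 0) {
    peak[core_idx] <- sample(DEV_STAGES, n_core, replace = TRUE)
    fold[core_idx] <- runif(n_core, config$fold_change_range[1],
                            config$fold_change_range[2])
  }
  rate <- ifelse(!is.na(peak) & peak %in% c("t3", "t4"),
                 config$substitution_rate_late_peak,
                 config$substitution_rate_early_peak)

  len_aa_lo <- ceiling(config$cds_length_range[1] / 3)
  len_aa_hi <- floor(config$cds_length_range[2] / 3)

  fam_records <- vector("list", n_fam)
  for (i in seq_len(n_fam)) {
    P <- sample(len_aa_lo:len_aa_hi, 1)
    anc <- sample.int(20L, P, replace = TRUE)
    # planted core families are conserved one-per-species by definition
    # (the truth category is "conserved core with orthologs in all four
    # species"); birth-death events apply to the non-core background
    dup_p <- if (is_core[i]) 0 else config$duplication_prob
    loss_p <- if (is_core[i]) 0 else config$loss_prob
    tips <- evolve_tree(anc, rate[i], dup_p, loss_p)
    recs <- list()
    for (sp in SPECIES) {
      copies <- tips[[sp]]
      if (length(copies) == 0) next
      for (k in seq_along(copies)) {
        recs[[length(recs) + 1L]] <- tibble::tibble(
          gene_id = sprintf("%s_%s_c%d", sp, fam_ids[i], k),
          species = sp,
          cds_length_nt = 3L * P,
          protein = paste(AA20[copies[[k]]], collapse = ""),
          truth_family = fam_ids[i],
          truth_core_dev = is_core[i],
          truth_peak_stage = peak[i],
          truth_fold = fold[i]
        )
      }
    }
    fam_records[[i]] <- dplyr::bind_rows(recs)
  }
  catalogue <- dplyr::bind_rows(fam_records)

  # species-specific singletons
  n_sp <- config$n_species_specific_per_species
  sp_records <- list()
  for (sp in SPECIES) {
    if (n_sp == 0) next
    n_dev <- round_half_up(config$frac_species_specific_dev * n_sp)
    dev_idx <- if (n_dev > 0) sort(sample.int(n_sp, n_dev)) else integer(0)
    for (i in seq_len(n_sp)) {
      P <- sample(len_aa_lo:len_aa_hi, 1)
      planted <- i %in% dev_idx
      sp_records[[length(sp_records) + 1L]] <- tibble::tibble(
        gene_id = sprintf("%s_s%04d", sp, i),
        species = sp,
        cds_length_nt = 3L * P,
        protein = paste(AA20[sample.int(20L, P, replace = TRUE)],
                        collapse = ""),
        truth_family = NA_character_,
        truth_core_dev = FALSE,
        truth_peak_stage = if (planted) sample(DEV_STAGES, 1) else NA_character_,
        truth_fold = if (planted) {
          runif(1, config$fold_change_range[1], config$fold_change_range[2])
        } else NA_real_
      )
    }
  }
  catalogue <- dplyr::bind_rows(catalogue, dplyr::bind_rows(sp_records)) |>
    dplyr::arrange(.data$species, .data$gene_id)

  surviving_core <- catalogue |>
    dplyr::filter(.data$truth_core_dev) |>
    dplyr::pull(.data$truth_family) |>
    unique() |>
    sort()

  planted <- catalogue |> dplyr::filter(!is.na(.data$truth_peak_stage))
  per_species_up <- lapply(
    setNames(SPECIES, SPECIES),
    function(sp) planted$gene_id[planted$species == sp]
  )
  peak_map <- setNames(planted$truth_peak_stage, planted$gene_id)

  list(
    catalogue = catalogue,
    truth = list(
      core_dev_families = surviving_core,
      per_species_upregulated = per_species_up,
      peak_stage = peak_map
    )
  )
}

# one Poisson round of substitutions on an integer-coded protein
mutate_protein <- function(seq, rate) {
  P <- length(seq)
  n <- rpois(1, rate * P)
  if (n > 0) {
    pos <- sample.int(P, n, replace = TRUE)
    # uniform over the 19 other residues
    shift <- sample.int(19L, n, replace = TRUE)
    seq[pos] <- ((seq[pos] - 1L + shift) %% 20L) + 1L
  }
  seq
}

# evolve one copy set along one branch: loss, substitution, duplication
evolve_branch <- function(copies, rate, dup_p, loss_p) {
  out <- list()
  for (cp in copies) {
    if (runif(1) < loss_p) next
    out[[length(out) + 1L]] <- mutate_protein(cp, rate)
    if (runif(1) < dup_p) out[[length(out) + 1L]] <- mutate_protein(cp, rate)
  }
  out
}

# fixed topology ((DF,PP),(DL,DD)); all branch lengths 1
evolve_tree <- function(anc, rate, dup_p, loss_p) {
  anc_fp <- evolve_branch(list(anc), rate, dup_p, loss_p) # root -> (DF,PP)
  anc_ld <- evolve_branch(list(anc), rate, dup_p, loss_p) # root -> (DL,DD)
  list(
    DF = evolve_branch(anc_fp, rate, dup_p, loss_p),
    PP = evolve_branch(anc_fp, rate, dup_p, loss_p),
    DL = evolve_branch(anc_ld, rate, dup_p, loss_p),
    DD = evolve_branch(anc_ld, rate, dup_p, loss_p)
  )
}
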