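#' Configuration for the synthetic four-species developmental transcriptome
#'
#' Bundles every knob of the synthetic-data generator: a four-species gene
#' family landscape on the fixed topology `((DF,PP),(DL,DD))`, negative
#' binomial stage-count matrices over the five developmental stages
#' (growth t0 through late fruiting t4) with a planted set of conserved
#' developmentally up-regulated families, stage-asynchrony signal mixing,
#' and peak-stage-dependent protein substitution rates encoding higher
#' conservation of late-peaking genes.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param n_families_conserved number of ancestral gene families shared by
#'   all four species (before lineage-specific duplication/loss).
#' @param n_species_specific_per_species number of singleton genes private to
#'   each species.
#' @param frac_core_dev fraction of conserved families planted as
#'   developmentally up-regulated in all four species.
#' @param fold_change_range `c(low, high)`: planted peak fold changes are
#'   drawn uniformly from this interval (one draw per family, shared by all
#'   orthologs of the family).
#' @param dispersion negative binomial dispersion alpha; counts have
#'   variance `mu + alpha * mu^2`.
#' @param library_size_per_stage expected total reads per stage column.
#' @param asynchrony_mix proportion in `[0, 1)` of a stage's expected signal
#'   borrowed from its neighbouring stages, applied to the less synchronously
#'   developing species (DL, PP, DF).
#' @param substitution_rate_early_peak,substitution_rate_late_peak per-site
#'   per-branch amino-acid substitution rates for early-peaking (t1/t2, and
#'   non-developmental background) versus late-peaking (t3/t4) families; the
#'   late rate must be lower.
#' @param duplication_prob,loss_prob per-branch per-copy probabilities of a
#'   gene duplication or loss on the species tree.
#' @param frac_species_specific_dev fraction of the species-specific
#'   singletons planted as developmentally up-regulated in their own species.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-family baseline expression level (rpkm scale).
#' @param member_jitter_sdlog log-normal sd of the per-gene jitter applied
#'   around the family baseline (orthologs keep comparable levels, which is
#'   what makes species usable as evolutionary replicates).
#' @param strain_jitter_sdlog log-normal sd of the per-gene jitter between
#'   the two D. discoideum strains (NC4 vs AX4).
#' @param cds_length_range CDS length bounds in nucleotides; lengths are
#'   drawn uniformly in multiples of 3.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_families_conserved = 20)
#' @export
sim_config <- function(seed = 1L,
                       n_families_conserved = 200L,
                       n_species_specific_per_species = 30L,
                       frac_core_dev = 0.15,
                       fold_change_range = c(4, 20),
                       dispersion = 0.2,
                       library_size_per_stage = 2e6,
                       asynchrony_mix = 0.3,
                       substitution_rate_early_peak = 0.12,
                       substitution_rate_late_peak = 0.05,
                       duplication_prob = 0.05,
                       loss_prob = 0.05,
                       frac_species_specific_dev = 0.2,
                       baseline_meanlog = 3,
                       baseline_sdlog = 1,
                       member_jitter_sdlog = 0.25,
                       strain_jitter_sdlog = 0.15,
                       cds_length_range = c(300, 3000)) {
  cfg <- list(
    seed = seed,
    n_families_conserved = n_families_conserved,
    n_species_specific_per_species = n_species_specific_per_species,
    frac_core_dev = frac_core_dev,
    fold_change_range = fold_change_range,
    dispersion = dispersion,
    library_size_per_stage = library_size_per_stage,
    asynchrony_mix = asynchrony_mix,
    substitution_rate_early_peak = substitution_rate_early_peak,
    substitution_rate_late_peak = substitution_rate_late_peak,
    duplication_prob = duplication_prob,
    loss_prob = loss_prob,
    frac_species_specific_dev = frac_species_specific_dev,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    member_jitter_sdlog = member_jitter_sdlog,
    strain_jitter_sdlog = strain_jitter_sdlog,
    cds_length_range = cds_length_range
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

cfg_fail <- function(field, why) {
  stop(sprintf("invalid configuration field '%s': %s", field, why),
       call. = FALSE)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, allow_zero = FALSE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) ||
        x < if (allow_zero) 0 else 1)
      cfg_fail(field, "must be a positive whole number")
  }
  chk_frac <- function(field, lo = 0, hi = 1, open_hi = FALSE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi ||
        (open_hi && x >= hi))
      cfg_fail(field, sprintf("must lie in [%g, %g%s", lo, hi,
                              if (open_hi) ")" else "]"))
  }
  chk_pos <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      cfg_fail(field, "must be a positive real")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed != floor(cfg$seed))
    cfg_fail("seed", "must be a single integer")
  chk_count("n_families_conserved")
  chk_count("n_species_specific_per_species", allow_zero = TRUE)
  chk_frac("frac_core_dev")
  fc <- cfg$fold_change_range
  if (!is.numeric(fc) || length(fc) != 2 || any(is.na(fc)) || any(fc <= 0) ||
      fc[1] > fc[2])
    cfg_fail("fold_change_range", "must be an increasing pair of positive reals")
  chk_pos("dispersion")
  chk_count("library_size_per_stage")
  chk_frac("asynchrony_mix", open_hi = TRUE)
  if (!is.numeric(cfg$substitution_rate_early_peak) ||
      cfg$substitution_rate_early_peak < 0)
    cfg_fail("substitution_rate_early_peak", "must be a non-negative real")
  if (!is.numeric(cfg$substitution_rate_late_peak) ||
      cfg$substitution_rate_late_peak < 0)
    cfg_fail("substitution_rate_late_peak", "must be a non-negative real")
  if (cfg$substitution_rate_late_peak > cfg$substitution_rate_early_peak)
    cfg_fail("substitution_rate_late_peak",
             "must not exceed substitution_rate_early_peak (late-peaking genes are the more conserved)")
  chk_frac("duplication_prob")
  chk_frac("loss_prob")
  chk_frac("frac_species_specific_dev")
  chk_pos("baseline_sdlog")
  if (!is.numeric(cfg$baseline_meanlog) || length(cfg$baseline_meanlog) != 1)
    cfg_fail("baseline_meanlog", "must be a single real")
  if (cfg$member_jitter_sdlog < 0) cfg_fail("member_jitter_sdlog", "must be >= 0")
  if (cfg$strain_jitter_sdlog < 0) cfg_fail("strain_jitter_sdlog", "must be >= 0")
  cl <- cfg$cds_length_range
  if (!is.numeric(cl) || length(cl) != 2 || cl[1] < 3 || cl[1] > cl[2])
    cfg_fail("cds_length_range", "must be an increasing pair with lower bound >= 3")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-32s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
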