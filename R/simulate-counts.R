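#' Simulate negative binomial stage-count tables
#'
#' Draws read counts for every gene over the five developmental stages
#' (t0 growth ... t4 late fruiting), one table per species plus an `AX4`
#' table for the second D. discoideum strain. Planted genes follow a
#' unimodal expression program: log2 signal rises linearly from the growth
#' baseline to `log2(fold)` at the truth peak stage and decays by half (in
#' log space) per stage afterwards. Stage asynchrony is modelled as
#' adjacent-stage signal mixing and applied to the species that develop
#' less synchronously (DL, PP, DF):
#' `signal'(s) = (1 - a) * signal(s) + a/2 * (signal(s-1) + signal(s+1))`,
#' edge stages mixing with their single neighbour at `a/2`.
#'
#' Expected values are scaled so each stage column sums to
#' `library_size_per_stage`; counts are negative binomial with variance
#' `mu + dispersion * mu^2`. Baseline expression is drawn per family
#' (log-normal, rpkm scale) with small per-gene jitter, so orthologs keep
#' comparable levels across species.
#'
#' @param catalogue,truth as returned by [simulate_families()].
#' @param config the same [sim_config()].
#' @return named list of tibbles (`DD`, `DL`, `PP`, `DF`, `AX4`), each with
#'   columns `gene_id`, `t0` ... `t4` (integer counts). `AX4` covers the DD
#'   genes.
#' @examples
#' cfg <- sim_config(seed = 1, n_families_conserved = 10)
#' sim <- simulate_families(cfg)
#' counts <- simulate_counts(sim$catalogue, sim$truth, cfg)
#' names(counts)
#' @export
simulate_counts <- function(catalogue, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  truth_genes <- unique(c(unlist(truth$per_species_upregulated),
                          names(truth$peak_stage)))
  missing <- setdiff(truth_genes, catalogue$gene_id)
  if (length(missing) > 0)
    stop("truth/catalogue inconsistency: gene(s) in truth absent from catalogue: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)

  set.seed(config$seed + 1L) # counts stream, derived from the config seed
  cat_sorted <- dplyr::arrange(catalogue, .data$species, .data$gene_id)

  # family baselines (rpkm scale), then per-gene jitter
  fams <- sort(unique(stats::na.omit(cat_sorted$truth_family)))
  fam_base <- setNames(
    rlnorm(length(fams), config$baseline_meanlog, config$baseline_sdlog),
    fams
  )
  gene_base <- ifelse(
    is.na(cat_sorted$truth_family),
    rlnorm(nrow(cat_sorted), config$baseline_meanlog, config$baseline_sdlog),
    unname(fam_base[cat_sorted$truth_family]) *
      rlnorm(nrow(cat_sorted), 0, config$member_jitter_sdlog)
  )
  names(gene_base) <- cat_sorted$gene_id
  dd_ids <- cat_sorted$gene_id[cat_sorted$species == "DD"]
  ax4_base <- gene_base[dd_ids] *
    rlnorm(length(dd_ids), 0, config$strain_jitter_sdlog)
  names(ax4_base) <- dd_ids

  profile_of <- function(peak, fold) {
    if (is.na(peak)) return(rep(1, 5))
    planted_profile(fold, peak)
  }

  draw_table <- function(ids, base, mixed) {
    sub <- cat_sorted[match(ids, cat_sorted$gene_id), ]
    if (length(ids) == 0) {
      return(tibble::tibble(gene_id = character(),
                            t0 = integer(), t1 = integer(), t2 = integer(),
                            t3 = integer(), t4 = integer()))
    }
    prof <- t(vapply(seq_along(ids), function(i) {
      profile_of(sub$truth_peak_stage[i], sub$truth_fold[i])
    }, numeric(5)))
    if (mixed && config$asynchrony_mix > 0) {
      prof <- t(apply(prof, 1, mix_profile, a = config$asynchrony_mix))
    }
    w <- prof * base[ids] * sub$cds_length_nt # expected reads ~ rpkm * length
    mu <- sweep(w, 2, colSums(w), "/") * config$library_size_per_stage
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion),
      nrow = nrow(mu)
    )
    out <- tibble::as_tibble(counts, .name_repair = "minimal")
    names(out) <- STAGES
    dplyr::bind_cols(tibble::tibble(gene_id = ids), out)
  }

  out <- list()
  for (sp in SPECIES) {
    ids <- cat_sorted$gene_id[cat_sorted$species == sp]
    out[[sp]] <- draw_table(ids, gene_base, mixed = sp != "DD")
  }
  out[["AX4"]] <- draw_table(dd_ids, ax4_base, mixed = FALSE)
  out
}

# log-linear rise from baseline (t0) to log2(fold) at the peak stage, then
# log-space decay by half per subsequent stage; linear-scale output over
# the 5 stages
planted_profile <- function(fold, peak) {
  p <- match(peak, STAGES) - 1 # peak index 1..4
  l2 <- numeric(5)
  lf <- log2(fold)
  for (s in 1:4) {
    l2[s + 1] <- if (s <= p) lf * s / p else lf * 0.5^(s - p)
  }
  2^l2
}

# Adjacent-stage mixing over the developmental stages t1..t4; edge stages
# (t1, t4) mix with their single neighbour at a/2. The growth sample t0 is
# left untouched: it is harvested from suspension culture before
# development starts, so developmental asynchrony cannot contaminate it.
mix_profile <- function(x, a) {
  d <- x[2:5]
  n <- length(d)
  left <- c(0, d[-n])
  right <- c(d[-1], 0)
  c(x[1], (1 - a) * d + (a / 2) * (left + right))
}
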