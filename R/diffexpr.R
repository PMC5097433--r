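#' Build a replicate design for the NB differential-expression engine
#'
#' Method B treats the four species as "evolutionary replicates": only
#' families with exactly one member per species are admitted as units, and
#' the unit's counts in a sample are the counts of that species' member at
#' that stage. Method C treats the two D. discoideum strains (NC4, AX4) as
#' replicates with DD genes as units.
#'
#' @param counts_by_species named list of count tibbles (needs `DD`, `DL`,
#'   `PP`, `DF`).
#' @param families tibble `family_id`, `gene_id`, `species`.
#' @return list of class `replicate_design`: `counts` (units x samples
#'   integer matrix), `samples` (tibble `sample`, `replicate`, `stage`),
#'   `unit_map` (tibble `unit_id`, `species`/`strain`, `gene_id`).
#' @export
design_species_replicates <- function(counts_by_species, families) {
  per <- families |>
    dplyr::count(.data$family_id, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L)
  for (sp in setdiff(SPECIES, names(per))) per[[sp]] <- 0L
  ok <- apply(as.matrix(per[, SPECIES]) == 1, 1, all)
  admitted <- per$family_id[ok]
  fam <- families |> dplyr::filter(.data$family_id %in% admitted)
  samples <- tidyr::expand_grid(replicate = SPECIES, stage = STAGES) |>
    dplyr::mutate(sample = paste(.data$replicate, .data$stage, sep = ":"))
  counts <- matrix(0L, nrow = length(admitted), ncol = nrow(samples),
                   dimnames = list(sort(admitted), samples$sample))
  for (sp in SPECIES) {
    tab <- counts_by_species[[sp]]
    members <- fam |> dplyr::filter(.data$species == sp)
    idx <- match(members$gene_id, tab$gene_id)
    if (anyNA(idx))
      stop("family member missing from ", sp, " count table", call. = FALSE)
    for (s in STAGES) {
      counts[members$family_id, paste(sp, s, sep = ":")] <- tab[[s]][idx]
    }
  }
  structure(
    list(counts = counts, samples = samples,
         unit_map = fam |> dplyr::select("family_id", "species", "gene_id") |>
           dplyr::rename(unit_id = "family_id")),
    class = "replicate_design"
  )
}

#' @rdname design_species_replicates
#' @param counts_nc4,counts_ax4 count tibbles for the two DD strains; genes
#'   present in both are used as units.
#' @export
design_strain_replicates <- function(counts_nc4, counts_ax4) {
  genes <- sort(intersect(counts_nc4$gene_id, counts_ax4$gene_id))
  strains <- c("NC4", "AX4")
  samples <- tidyr::expand_grid(replicate = strains, stage = STAGES) |>
    dplyr::mutate(sample = paste(.data$replicate, .data$stage, sep = ":"))
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                   dimnames = list(genes, samples$sample))
  for (tab_nm in strains) {
    tab <- if (tab_nm == "NC4") counts_nc4 else counts_ax4
    idx <- match(genes, tab$gene_id)
    for (s in STAGES) {
      counts[, paste(tab_nm, s, sep = ":")] <- tab[[s]][idx]
    }
  }
  structure(
    list(counts = counts, samples = samples,
         unit_map = tibble::tibble(unit_id = genes, strain = NA_character_,
                                   gene_id = genes)),
    class = "replicate_design"
  )
}

#' Median-of-ratios size factors
#'
#' `s_j = median_i k_ij / geomean_i` over units `i` whose counts are
#' positive in every sample (so the geometric mean is positive), the
#' normalisation underlying DESeq-style analyses.
#'
#' @param count_matrix units x samples non-negative matrix.
#' @return named numeric vector of size factors, one per sample (column).
#' @export
size_factors <- function(count_matrix) {
  m <- as.matrix(count_matrix)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no unit has all-positive counts; filter low-count units first",
         call. = FALSE)
  lg <- log(m[pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  apply(m[pos, , drop = FALSE], 2, function(col) median(col / geo))
}

#' Per-unit dispersion with a 1/mean trend and conservative sharing
#'
#' Raw dispersion by method of moments within conditions,
#' `alpha = max(0, (s^2 - mean) / mean^2)` pooled across conditions with
#' degrees-of-freedom weights; a trend `alpha(mu) = a0 + a1 / mu` fitted by
#' least squares over units; the final value is the conservative maximum of
#' raw and trend, floored at `alpha_floor`.
#'
#' @param norm_counts units x samples matrix of normalised counts
#'   (counts / size factor).
#' @param condition character/factor of length `ncol(norm_counts)` labelling
#'   the condition (stage) of each sample; at least one condition needs two
#'   or more replicates.
#' @param alpha_floor lower bound on the final dispersion.
#' @return tibble `unit_id`, `base_mean`, `raw_alpha`, `fitted_alpha`,
#'   `final_alpha`.
#' @export
estimate_dispersion <- function(norm_counts, condition, alpha_floor = 1e-8) {
  m <- as.matrix(norm_counts)
  condition <- as.character(condition)
  reps <- table(condition)
  if (all(reps < 2))
    stop("dispersion not estimable: no condition has >= 2 replicates",
         call. = FALSE)
  conds <- names(reps)[reps >= 2]
  raw <- vapply(seq_len(nrow(m)), function(i) {
    num <- 0; den <- 0
    for (cc in conds) {
      x <- m[i, condition == cc]
      mu <- mean(x)
      if (mu <= 0) next
      a <- (var(x) - mu) / mu^2
      w <- length(x) - 1
      num <- num + w * a
      den <- den + w
    }
    if (den == 0) return(0)
    max(0, num / den)
  }, numeric(1))
  base_mean <- rowMeans(m)
  ok <- base_mean > 0
  fitted_alpha <- rep(alpha_floor, nrow(m))
  if (sum(ok) >= 2 && stats::sd(1 / base_mean[ok]) > 0) {
    fit <- lm(raw[ok] ~ I(1 / base_mean[ok]))
    fitted_alpha[ok] <- pmax(coef(fit)[1] + coef(fit)[2] / base_mean[ok], 0)
  }
  tibble::tibble(
    unit_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    base_mean = base_mean,
    raw_alpha = raw,
    fitted_alpha = fitted_alpha,
    final_alpha = pmax(pmax(raw, fitted_alpha), alpha_floor)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Negative binomial Wald test of one stage against growth
#'
#' Fits `mu_j = s_j * exp(b0 + b1 * x_j)` (x = 1 for the contrasted stage,
#' 0 for t0) to the unit's counts across replicates by Newton-Raphson with
#' the dispersion held fixed, and tests `b1 = 0` with a two-sided Wald test
#' using the observed-information standard error.
#' `log2_fold_change = b1 / ln 2`.
#'
#' @param y counts for one unit across the t0 and stage-s samples.
#' @param sf size factors for those samples.
#' @param x 0/1 indicator of the contrasted stage.
#' @param alpha NB dispersion for the unit.
#' @param max_iter,tol Newton iteration controls (|delta beta| < tol).
#' @return one-row tibble: `base_mean`, `log2_fold_change`, `p_value`,
#'   `flag` ("ok", "all_zero", "not_converged").
#' @export
nb_stage_test <- function(y, sf, x, alpha, max_iter = 50, tol = 1e-8) {
  stopifnot(length(y) == length(sf), length(y) == length(x))
  base_mean <- mean(y / sf)
  if (all(y == 0)) {
    return(tibble::tibble(base_mean = 0, log2_fold_change = 0, p_value = 1,
                          flag = "all_zero"))
  }
  eps <- 0.5
  m0 <- max(mean((y / sf)[x == 0]), eps)
  m1 <- max(mean((y / sf)[x == 1]), eps)
  beta <- c(log(m0), log(m1 / m0))
  X <- cbind(1, x)
  flag <- "not_converged"
  for (it in seq_len(max_iter)) {
    eta <- log(sf) + X %*% beta
    mu <- pmin(exp(eta), 1e12)
    w <- as.vector(mu / (1 + alpha * mu))
    score <- t(X) %*% ((y - mu) / (1 + alpha * mu))
    info <- t(X) %*% (X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta <- beta + as.vector(step)
    beta <- pmin(pmax(beta, -50), 50)
    if (max(abs(step)) < tol) {
      flag <- "ok"
      break
    }
  }
  if (flag != "ok") {
    return(tibble::tibble(base_mean = base_mean, log2_fold_change = 0,
                          p_value = 1, flag = flag))
  }
  eta <- log(sf) + X %*% beta
  mu <- pmin(exp(eta), 1e12)
  w <- as.vector(mu / (1 + alpha * mu))
  info <- t(X) %*% (X * w)
  se <- sqrt(solve(info)[2, 2])
  z <- beta[2] / se
  tibble::tibble(base_mean = base_mean,
                 log2_fold_change = beta[2] / log(2),
                 p_value = 2 * pnorm(-abs(z)),
                 flag = "ok")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around the standard step-up procedure:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Call developmentally up-regulated units at a target FDR
#'
#' Runs the full NB engine on a replicate design: median-of-ratios size
#' factors, dispersion estimation across stages, one Wald contrast per
#' developmental stage against t0 per unit, Benjamini-Hochberg across all
#' (unit, stage) pairs, and an up-direction filter. A unit is called when
#' some stage has `q <= fdr` with a positive log2 fold change.
#'
#' @param design a `replicate_design`.
#' @param fdr target false discovery rate (default 0.10).
#' @return object of class `nb_de`: `results` tibble (`unit_id`, `stage`,
#'   `base_mean`, `log2_fold_change`, `p_value`, `q_value`, `called_up`,
#'   `flag`), `called` (character vector of unit ids), `size_factors`,
#'   `dispersions`, `fdr`.
#' @export
call_method <- function(design, fdr = 0.10) {
  stopifnot(inherits(design, "replicate_design"))
  m <- design$counts
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  disp <- estimate_dispersion(norm, design$samples$stage)
  alpha <- setNames(disp$final_alpha, disp$unit_id)
  res <- list()
  for (s in DEV_STAGES) {
    sel <- design$samples$stage %in% c("t0", s)
    x <- as.integer(design$samples$stage[sel] == s)
    sfs <- sf[sel]
    for (i in seq_len(nrow(m))) {
      uid <- rownames(m)[i]
      r <- nb_stage_test(m[i, sel], sfs, x, alpha[[uid]])
      r$unit_id <- uid
      r$stage <- s
      res[[length(res) + 1L]] <- r
    }
  }
  results <- dplyr::bind_rows(res) |>
    dplyr::select("unit_id", "stage", "base_mean", "log2_fold_change",
                  "p_value", "flag")
  results$q_value <- bh_adjust(results$p_value)
  results$called_up <- results$q_value <= fdr & results$log2_fold_change > 0
  called <- sort(unique(results$unit_id[results$called_up]))
  structure(
    list(results = results, called = called, size_factors = sf,
         dispersions = disp, fdr = fdr, design = design),
    class = "nb_de"
  )
}

#' @export
print.nb_de <- function(x, ...) {
  cat(sprintf("<nb_de> %d units, %d called up-regulated at FDR %.2g\n",
              length(unique(x$results$unit_id)), length(x$called), x$fdr))
  invisible(x)
}

#' Methods B and C
#'
#' `method_b()` runs the NB engine with the four species as evolutionary
#' replicates over one-per-species ortholog families; `method_c()` runs it
#' with the two D. discoideum strains (NC4 = the package's DD table, AX4)
#' as replicates over DD genes. Both call up-regulation at a 10 % FDR by
#' default.
#'
#' @param counts_by_species named list of count tibbles (`DD`, `DL`, `PP`,
#'   `DF`).
#' @param families families tibble.
#' @param fdr target FDR.
#' @return an `nb_de` object (see [call_method()]).
#' @export
method_b <- function(counts_by_species, families, fdr = 0.10) {
  call_method(design_species_replicates(counts_by_species, families), fdr)
}

#' @rdname method_b
#' @param counts_nc4,counts_ax4 DD count tibbles for the two strains.
#' @export
method_c <- function(counts_nc4, counts_ax4, fdr = 0.10) {
  call_method(design_strain_replicates(counts_nc4, counts_ax4), fdr)
}
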