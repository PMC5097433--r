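#' Global alignment percent identity
#'
#' Needleman-Wunsch global alignment with a simple scheme (match +1,
#' mismatch -1, linear gap -2) and a fixed traceback preference
#' (diagonal > up > left, "up" consuming a residue of `seq_a`), so results
#' are deterministic. Identity is identical aligned positions divided by
#' the alignment length including gaps.
#'
#' @param seq_a,seq_b non-empty protein strings.
#' @return one-row tibble: `score`, `percent_identity`, `align_length`,
#'   `n_identical`.
#' @examples
#' align_percent_identity("KWYE", "KWYD")
#' @export
align_percent_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("empty sequence", call. = FALSE)
  r <- .nw_align_cpp(seq_a, seq_b)
  tibble::tibble(score = r$score, percent_identity = r$identity,
                 align_length = r$align_length, n_identical = r$n_identical)
}

#' DD-DF conservation records for a gene set
#'
#' Pairs each D. discoideum gene in `gene_set` with its D. fasciculatum
#' ortholog (families with exactly one DD and one DF member), aligns the two
#' proteins globally and records percent identity together with the DD
#' expression peak stage.
#'
#' @param gene_set character vector of DD gene ids (e.g. the defined
#'   developmental set).
#' @param families tibble `family_id`, `gene_id`, `species`.
#' @param catalogue gene catalogue with `gene_id`, `protein`.
#' @param profiles_dd DD profile tibble from [compute_rpkm()] (for
#'   `peak_stage`).
#' @return tibble: `dd_gene_id`, `df_gene_id`, `percent_identity`,
#'   `peak_stage`.
#' @export
conservation_records <- function(gene_set, families, catalogue,
                                 profiles_dd) {
  pairs <- families |>
    dplyr::filter(.data$species %in% c("DD", "DF")) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::filter(sum(.data$species == "DD") == 1,
                  sum(.data$species == "DF") == 1) |>
    dplyr::summarise(
      dd_gene_id = .data$gene_id[.data$species == "DD"],
      df_gene_id = .data$gene_id[.data$species == "DF"],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$dd_gene_id %in% gene_set)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(dd_gene_id = character(), df_gene_id = character(),
                          percent_identity = double(),
                          peak_stage = character()))
  }
  prot <- setNames(catalogue$protein, catalogue$gene_id)
  peak <- setNames(profiles_dd$peak_stage, profiles_dd$gene_id)
  pairs |>
    dplyr::mutate(
      percent_identity = purrr::map2_dbl(
        .data$dd_gene_id, .data$df_gene_id,
        function(a, b) align_percent_identity(prot[[a]], prot[[b]])$percent_identity
      ),
      peak_stage = unname(peak[.data$dd_gene_id])
    ) |>
    dplyr::select("dd_gene_id", "df_gene_id", "percent_identity",
                  "peak_stage")
}

#' Are late-peaking genes more conserved? (Mann-Whitney U)
#'
#' One-sided Wilcoxon-Mann-Whitney test of the hypothesis that percent
#' identities of genes peaking at the late stages (default t3/t4, pooled)
#' are stochastically greater than those of genes peaking early (default
#' t1). The p-value is exact for small untied samples and uses the normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param records tibble from [conservation_records()] (needs
#'   `percent_identity`, `peak_stage`).
#' @param late_stages,early_stage stage labels defining the two groups.
#' @return object of class `conservation_test`: `statistic` (U of the late
#'   group), `p_value`, `n_late`, `n_early`, `median_late`, `median_early`,
#'   `method`.
#' @export
conservation_by_peak <- function(records, late_stages = c("t3", "t4"),
                                 early_stage = "t1") {
  late <- records$percent_identity[records$peak_stage %in% late_stages]
  early <- records$percent_identity[records$peak_stage %in% early_stage]
  if (length(late) == 0 || length(early) == 0)
    stop("empty group: need at least one gene peaking in each of the ",
         "late and early stage sets", call. = FALSE)
  exact <- (length(late) + length(early)) <= 20 &&
    !any(duplicated(c(late, early)))
  wt <- suppressWarnings(
    wilcox.test(late, early, alternative = "greater", exact = exact,
                correct = TRUE)
  )
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_late = length(late), n_early = length(early),
         median_late = median(late), median_early = median(early),
         method = if (exact) "exact" else "normal approximation"),
    class = "conservation_test"
  )
}

#' @export
print.conservation_test <- function(x, ...) {
  cat(sprintf(
    "<conservation_test> U = %g, one-sided p = %.4g (%s)\n  late  (n=%d): median identity %.3f\n  early (n=%d): median identity %.3f\n",
    x$statistic, x$p_value, x$method, x$n_late, x$median_late,
    x$n_early, x$median_early))
  invisible(x)
}
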