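#' Expression profiles: rpkm, peak stage, fold change over growth
#'
#' Computes `rpkm(g, s) = 1e9 * count(g, s) / (length_nt(g) *
#' column_total(s))` for every gene over the five stages, the developmental
#' peak stage (argmax of rpkm over t1..t4, ties broken toward the later
#' stage), and the maximum fold change of any developmental stage over the
#' growth sample, with the t0 denominator floored at `epsilon` rpkm to keep
#' silent-at-growth genes finite.
#'
#' @param counts tibble `gene_id`, `t0` ... `t4` (raw counts).
#' @param gene_lengths tibble with `gene_id` and `cds_length_nt` (a gene
#'   catalogue works), or a named numeric vector.
#' @param epsilon rpkm floor for the t0 denominator.
#' @param min_reads read floor used to set `passes_read_floor` (a gene
#'   passes when some stage has at least this many raw reads).
#' @return tibble: `gene_id`, `rpkm_t0` ... `rpkm_t4`, `max_count`,
#'   `peak_stage`, `max_fold_vs_t0`, `passes_read_floor`.
#' @export
compute_rpkm <- function(counts, gene_lengths, epsilon = 0.5,
                         min_reads = 20) {
  stopifnot(all(STAGES %in% names(counts)))
  if (!is.numeric(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$cds_length_nt, gene_lengths$gene_id)
  }
  lens <- gene_lengths[counts$gene_id]
  if (any(is.na(lens))) {
    bad <- counts$gene_id[which(is.na(lens))[1]]
    stop("missing CDS length for gene: ", bad, call. = FALSE)
  }
  mat <- as.matrix(counts[, STAGES])
  totals <- colSums(mat)
  if (any(totals == 0)) {
    stop("zero column total at stage: ", STAGES[which(totals == 0)[1]],
         call. = FALSE)
  }
  rpkm <- 1e9 * sweep(sweep(mat, 1, as.numeric(lens), "/"), 2, totals, "/")
  dev <- rpkm[, DEV_STAGES, drop = FALSE]
  # argmax over t1..t4, ties toward the later stage
  peak_idx <- apply(dev, 1, function(x) max(which(x == max(x))))
  fold <- apply(dev, 1, max) / pmax(rpkm[, "t0"], epsilon)
  out <- tibble::as_tibble(rpkm, .name_repair = "minimal")
  names(out) <- paste0("rpkm_", STAGES)
  dplyr::bind_cols(
    tibble::tibble(gene_id = counts$gene_id),
    out,
    tibble::tibble(
      max_count = apply(mat, 1, max),
      peak_stage = DEV_STAGES[peak_idx],
      max_fold_vs_t0 = fold,
      passes_read_floor = apply(mat, 1, max) >= min_reads
    )
  )
}

#' Method A: rpkm threshold caller for developmental up-regulation
#'
#' A gene is called developmentally up-regulated when it has at least
#' `min_reads` raw reads in some stage (excludes weakly expressed genes)
#' and its rpkm at some developmental stage is at least `min_fold` times
#' the growth (t0) value.
#'
#' @param profiles output of [compute_rpkm()].
#' @param min_reads raw-read floor (default 20).
#' @param min_fold fold-change threshold (default 3).
#' @return character vector of called gene ids.
#' @export
call_upregulated_a <- function(profiles, min_reads = 20, min_fold = 3) {
  profiles$gene_id[profiles$max_count >= min_reads &
                     profiles$max_fold_vs_t0 >= min_fold]
}

#' Group family members with similar expression patterns across species
#'
#' Families with exactly one member per represented species need no
#' matching: all members form one group. In larger families, members are
#' matched greedily across species by descending Pearson correlation of
#' their stage-wise `log2(rpkm + 1)` profiles: pairs are visited from the
#' strongest correlation down (lexicographic gene-id tie-break), and two
#' (groups of) genes are merged whenever the merged group still has at most
#' one member per species. Pairs below `min_similarity` never merge; a
#' zero-variance profile gets correlation 0 against everything.
#'
#' @param families tibble `family_id`, `gene_id`, `species`.
#' @param profiles combined profile tibble for all species
#'   (rows from [compute_rpkm()], any order).
#' @param min_similarity minimum Pearson correlation for a merge.
#' @return tibble `family_id`, `group_id`, `gene_id`, `species`; every
#'   family member appears in exactly one group (possibly alone).
#' @export
match_family_patterns <- function(families, profiles, min_similarity = 0.5) {
  rp <- as.matrix(profiles[, paste0("rpkm_", STAGES)])
  lp <- log2(rp + 1)
  rownames(lp) <- profiles$gene_id
  out <- families |>
    dplyr::group_by(.data$family_id) |>
    dplyr::group_modify(function(df, key) {
      match_one_family(df, lp, min_similarity)
    }) |>
    dplyr::ungroup()
  out
}

cor0 <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  cor(x, y)
}

match_one_family <- function(df, lp, min_similarity) {
  genes <- sort(df$gene_id)
  sp <- setNames(df$species, df$gene_id)[genes]
  one_per_species <- !anyDuplicated(sp)
  if (one_per_species) {
    return(tibble::tibble(group_id = "g1", gene_id = genes,
                          species = unname(sp)))
  }
  # greedy cross-species agglomeration
  group <- setNames(seq_along(genes), genes)
  pairs <- which(upper.tri(matrix(0, length(genes), length(genes))),
                 arr.ind = TRUE)
  keep <- sp[pairs[, 1]] != sp[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) > 0) {
    r <- vapply(seq_len(nrow(pairs)), function(k) {
      a <- genes[pairs[k, 1]]; b <- genes[pairs[k, 2]]
      if (!a %in% rownames(lp) || !b %in% rownames(lp)) return(NA_real_)
      cor0(lp[a, ], lp[b, ])
    }, numeric(1))
    ord <- order(-r, genes[pairs[, 1]], genes[pairs[, 2]])
    for (k in ord) {
      if (is.na(r[k]) || r[k] < min_similarity) break
      ga <- group[pairs[k, 1]]; gb <- group[pairs[k, 2]]
      if (ga == gb) next
      merged_sp <- sp[group %in% c(ga, gb)]
      if (anyDuplicated(merged_sp)) next
      group[group == gb] <- ga
    }
  }
  ids <- match(group, sort(unique(group)))
  tibble::tibble(group_id = paste0("g", ids), gene_id = genes,
                 species = unname(sp))
}

#' Assemble the DD-anchored Method A set (three-of-four rule)
#'
#' A D. discoideum gene enters the set when it is called up-regulated in DD,
#' its matched cross-species group spans at least `min_species` species, and
#' the group member is called in its own species in at least `min_species`
#' of them (counting DD itself). With the default `min_species = 3` this is
#' the three-of-four rule: groups restricted to three species must be called
#' in all three, four-species groups in at least three.
#'
#' @param called_by_species named list, species -> character vector of
#'   called gene ids ([call_upregulated_a()] per species).
#' @param matched_groups output of [match_family_patterns()].
#' @param min_species minimum number of species (counting DD) in which the
#'   group must be present and called.
#' @return list of class `method_a_call`: `dd_anchored_set` (character) and
#'   `per_species_upregulated` (the input call sets).
#' @export
assemble_method_a <- function(called_by_species, matched_groups,
                              min_species = 3) {
  called_all <- unlist(called_by_species, use.names = FALSE)
  grp <- matched_groups |>
    dplyr::group_by(.data$family_id, .data$group_id) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      n_called = sum(.data$gene_id %in% called_all),
      dd_called = any(.data$species == "DD" &
                        .data$gene_id %in% called_all),
      dd_genes = list(.data$gene_id[.data$species == "DD"]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$dd_called,
                  .data$n_species >= min_species,
                  .data$n_called >= min_species)
  dd_set <- sort(unique(unlist(grp$dd_genes)))
  dd_set <- intersect(dd_set, called_by_species[["DD"]])
  structure(
    list(dd_anchored_set = dd_set,
         per_species_upregulated = called_by_species),
    class = "method_a_call"
  )
}

#' @export
print.method_a_call <- function(x, ...) {
  cat(sprintf("<method_a_call> %d DD-anchored genes; per-species calls: %s\n",
              length(x$dd_anchored_set),
              paste(sprintf("%s=%d", names(x$per_species_upregulated),
                            lengths(x$per_species_upregulated)),
                    collapse = ", ")))
  invisible(x)
}

#' Run Method A end to end
#'
#' Convenience wrapper: per-species rpkm profiles, per-species threshold
#' calls, within-family expression-pattern matching, and the three-of-four
#' assembly into a DD-anchored gene set.
#'
#' @param counts_by_species named list (`DD`, `DL`, `PP`, `DF`) of count
#'   tibbles.
#' @param catalogue gene catalogue (for CDS lengths).
#' @param families families tibble (`family_id`, `gene_id`, `species`).
#' @param min_reads,min_fold,min_similarity,min_species see the individual
#'   steps.
#' @return a `method_a_call`, with the profile tables attached as
#'   `profiles`.
#' @export
method_a <- function(counts_by_species, catalogue, families,
                     min_reads = 20, min_fold = 3,
                     min_similarity = 0.5, min_species = 3) {
  profiles <- lapply(counts_by_species[SPECIES], compute_rpkm,
                     gene_lengths = catalogue, min_reads = min_reads)
  called <- lapply(profiles, call_upregulated_a,
                   min_reads = min_reads, min_fold = min_fold)
  groups <- match_family_patterns(families, dplyr::bind_rows(profiles),
                                  min_similarity = min_similarity)
  res <- assemble_method_a(called, groups, min_species = min_species)
  res$profiles <- profiles
  res$matched_groups <- groups
  res
}
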