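#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects: `tidy()` returns
#' the per-element table, `glance()` a one-row summary.
#'
#' @param x an `nb_de`, `core_report`, `conservation_test` or
#'   `method_a_call` object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.nb_de <- function(x, ...) x$results

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.nb_de <- function(x, ...) {
  tibble::tibble(
    n_units = length(unique(x$results$unit_id)),
    n_called = length(x$called),
    fdr = x$fdr
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.core_report <- function(x, ...) {
  tibble::tibble(region = names(x$venn_counts),
                 count = as.integer(x$venn_counts))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.core_report <- function(x, ...) {
  tibble::tibble(
    n_a = length(x$sets$A), n_b = length(x$sets$B), n_c = length(x$sets$C),
    union_size = x$union_size, core_size = length(x$core)
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.conservation_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    n_late = x$n_late, n_early = x$n_early,
    median_late = x$median_late, median_early = x$median_early,
    method = x$method
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.conservation_test <- function(x, ...) tidy.conservation_test(x, ...)

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.method_a_call <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$per_species_upregulated), function(sp) {
    tibble::tibble(species = sp, gene_id = x$per_species_upregulated[[sp]])
  }))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.method_a_call <- function(x, ...) {
  tibble::tibble(
    n_dd_anchored = length(x$dd_anchored_set),
    n_called_dd = length(x$per_species_upregulated$DD),
    n_called_dl = length(x$per_species_upregulated$DL),
    n_called_pp = length(x$per_species_upregulated$PP),
    n_called_df = length(x$per_species_upregulated$DF)
  )
}
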