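#' Plot expression profiles across developmental stages
#'
#' Line plot of rpkm (log2(rpkm + 1) scale) over the five stages for a set
#' of genes, one line per gene.
#'
#' @param profiles a profile tibble from [compute_rpkm()].
#' @param genes gene ids to show (default: first 20).
#' @return a ggplot object.
#' @export
plot_stage_profiles <- function(profiles, genes = head(profiles$gene_id, 20)) {
  df <- profiles |>
    dplyr::filter(.data$gene_id %in% genes) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("rpkm_", STAGES)),
                        names_to = "stage", values_to = "rpkm") |>
    dplyr::mutate(stage = factor(sub("rpkm_", "", .data$stage),
                                 levels = STAGES))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, log2(.data$rpkm + 1),
                                   group = .data$gene_id,
                                   colour = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.7, show.legend = length(genes) <= 12) +
    ggplot2::labs(x = "developmental stage", y = "log2(rpkm + 1)") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @param object a result object.
#' @exportS3Method ggplot2::autoplot
autoplot.core_report <- function(object, ...) {
  df <- tidy(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(.data$region, .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "Venn region (exclusive)", y = "genes",
                  title = "Method overlap") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @exportS3Method ggplot2::autoplot
autoplot.nb_de <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$base_mean + 1),
                                   .data$log2_fold_change,
                                   colour = .data$called_up)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log10 base mean + 1", y = "log2 fold change vs t0",
                  colour = "called up") +
    ggplot2::theme_minimal()
}

#' Conservation by expression peak stage
#'
#' Box plot of DD-DF percent identity for genes grouped by DD expression
#' peak stage, the visual companion of [conservation_by_peak()].
#'
#' @param records tibble from [conservation_records()].
#' @return a ggplot object.
#' @export
plot_conservation <- function(records) {
  df <- records |>
    dplyr::filter(!is.na(.data$peak_stage)) |>
    dplyr::mutate(peak_stage = factor(.data$peak_stage, levels = DEV_STAGES))
  ggplot2::ggplot(df, ggplot2::aes(.data$peak_stage,
                                   .data$percent_identity)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::labs(x = "DD expression peak stage",
                  y = "DD-DF percent identity") +
    ggplot2::theme_minimal()
}
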