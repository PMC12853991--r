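#' Boxplots of family abundance by phenotypic group
#'
#' RPKSM distributions per family, split by group role within each cohort,
#' on a log axis — the standard presentation for gene-family abundance in
#' stool metagenomes. Zero values are kept by a small pseudocount tied to
#' the smallest positive value.
#'
#' @param abundance An `rpksm_abundance` (or any long tibble with
#'   `family_id`, `sample_id`, `rpksm`).
#' @param samples Sample tibble with `sample_id`, `cohort`, `role`,
#'   `group`.
#' @param families Optional character vector restricting the plot.
#' @return A ggplot object.
#' @export
plot_abundance <- function(abundance, samples, families = NULL) {
  d <- abundance |>
    dplyr::inner_join(samples, by = "sample_id")
  if (!is.null(families)) {
    d <- d |> dplyr::filter(.data$family_id %in% families)
  }
  eps <- min(d$rpksm[d$rpksm > 0], na.rm = TRUE) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family_id,
                                  y = .data$rpksm + eps,
                                  fill = .data$role)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$cohort)) +
    ggplot2::labs(x = NULL, y = "RPKSM", fill = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Class-coded prevalence heatmap
#'
#' Clade-by-gene tile plot of prevalence classes (core / accessory /
#' highly accessory / absent).
#'
#' @param object An `rpksm_prevalence` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rpksm_prevalence <- function(object, ...) {
  cls <- c(core = "#1a9850", accessory = "#fee08b",
           highly_accessory = "#fdae61", absent = "grey85")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gene, y = .data$clade,
                                       fill = .data$class)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = cls, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "prevalence class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of plasmid gene content
#'
#' Number of distinct curated plasmids encoding at least one copy of each
#' gene.
#'
#' @param counts Tibble from [plasmid_gene_counts()].
#' @return A ggplot object.
#' @export
plot_plasmid_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$gene, -.data$n_plasmids),
    y = .data$n_plasmids)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::labs(x = NULL, y = "plasmids carrying the gene") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
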