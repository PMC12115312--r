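#' Copy-number heatmap
#'
#' Ortholog groups by genome/subgenome, tile fill giving the copy count;
#' absences (count 0) are drawn grey.
#'
#' @param cnv Wide CNV tibble from [build_cnv_matrix()].
#' @return A ggplot object.
#' @export
plot_cnv_heatmap <- function(cnv) {
  long <- tidyr::pivot_longer(cnv, -c("ortholog_group", "family"),
                              names_to = "genome", values_to = "copies")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome,
                                     y = .data$ortholog_group)) +
    ggplot2::geom_tile(ggplot2::aes(fill = ifelse(.data$copies == 0, NA,
                                                  .data$copies)),
                       colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$copies), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "#fee8c8", high = "#e34a33",
                                 na.value = "grey80", name = "copies") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$family), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Homoeolog-bias heatmap
#'
#' Pairs by tissue, coloured by bias category; expression shown as
#' log2(FPKM+1) of the pair total in the tile label scale.
#'
#' @param heb HEB call tibble from [classify_heb()].
#' @return A ggplot object.
#' @export
plot_heb <- function(heb) {
  ggplot2::ggplot(heb, ggplot2::aes(x = .data$tissue, y = .data$group)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$category), colour = "white") +
    ggplot2::scale_fill_manual(values = c(BALANCED = "grey70",
                                          DOM_A = "#2166ac",
                                          DOM_B = "#b2182b",
                                          NOT_EXPRESSED = "grey95")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "bias") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Expression-atlas heatmap
#'
#' Genes by tissue on the log10(FPKM + 0.01) display scale.
#'
#' @param atlas Result of [summarize_atlas()].
#' @return A ggplot object.
#' @export
plot_atlas <- function(atlas) {
  ggplot2::ggplot(atlas$tissue_means,
                  ggplot2::aes(x = .data$tissue, y = .data$gene_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$log10_display),
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "log10(FPKM+0.01)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
}

#' @rdname plot_heb
#' @param object A `kinase_pipeline`.
#' @param ... Unused.
#' @export
autoplot.kinase_pipeline <- function(object, ...) {
  plot_heb(object$heb)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
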