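#' Scatterplot of a strain-versus-strain expression contrast
#'
#' Log10-scaled replicate means of the two contrasted cells, with genes
#' passing the fold-change rule highlighted and filtered genes dimmed.
#'
#' @param records Contrast tibble from [classify_contrast()].
#' @param highlight Optional character vector of gene identifiers drawn in a
#'   separate colour (for example, known pathway genes).
#' @return A ggplot object.
#' @export
plot_contrast <- function(records, highlight = NULL) {
  df <- dplyr::mutate(
    records,
    status = dplyr::case_when(
      !is.null(highlight) & .data$gene_id %in% highlight ~ "highlighted",
      .data$call %in% c("up", "down") ~ "changed",
      .data$call == "filtered" ~ "below floor",
      TRUE ~ "unchanged"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_a + 0.1,
                                   y = .data$mean_b + 0.1,
                                   colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      "unchanged" = "grey30", "changed" = "red2",
      "highlighted" = "dodgerblue3", "below floor" = "grey80")) +
    ggplot2::labs(x = "mean FPKM (reference)", y = "mean FPKM (test)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of clustered expression profiles
#'
#' Z-scored log2 profiles of the clustered genes, rows ordered by the
#' dendrogram, with cluster labels on the strip.
#'
#' @param object A `regulon_clustering` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot regulon_clustering
#' @export
autoplot.regulon_clustering <- function(object, ...) {
  ord <- if (!is.null(object$hclust)) object$hclust$labels[object$hclust$order] else rownames(object$profiles)
  ord <- c(ord, setdiff(rownames(object$profiles), ord))
  df <- as_tibble(object$profiles, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "cell", values_to = "z") %>%
    dplyr::left_join(object$assignments, by = "gene_id") %>%
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$gene_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   strip.text.y = ggplot2::element_text(angle = 0))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of per-gene binding-site counts
#'
#' @param site_counts Tibble from [site_counts()].
#' @return A ggplot object.
#' @export
plot_site_histogram <- function(site_counts) {
  ggplot2::ggplot(site_counts, ggplot2::aes(x = .data$n_sites)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "binding sites per promoter", y = "genes") +
    ggplot2::theme_minimal()
}
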