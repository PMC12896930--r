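#' RLE box plot of a normalized matrix
#'
#' One box per sample of its relative log expression values; a well-behaved
#' normalization keeps the boxes tight and centered on zero.
#'
#' @param norm a [mir_norm()] or log2 expression matrix.
#' @return a ggplot.
#' @export
plot_rle <- function(norm) {
  vals <- rle_stats(norm)$values
  long <- tibble::tibble(
    sample_id = rep(colnames(vals), each = nrow(vals)),
    rle = as.vector(vals))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$rle)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "Relative log expression (log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Principal component plot of normalized samples
#' @param norm a [mir_norm()].
#' @param sheet sample sheet (colors the groups).
#' @return a ggplot.
#' @export
plot_pca <- function(norm, sheet) {
  y <- if (inherits(norm, "mir_norm")) norm$log2_expr else as.matrix(norm)
  pc <- stats::prcomp(t(y), center = TRUE, scale. = FALSE)
  pct <- round(100 * pc$sdev[1:2]^2 / sum(pc$sdev^2), 1)
  d <- tibble::tibble(sample_id = colnames(y), pc1 = pc$x[, 1], pc2 = pc$x[, 2]) |>
    dplyr::left_join(tibble::as_tibble(sheet), by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$pc1, .data$pc2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                  y = paste0("PC2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a fitted DE object
#' @param object a `mir_de`.
#' @param ... unused.
#' @return a ggplot, faceted by contrast.
#' @export
autoplot.mir_de <- function(object, ...) {
  d <- volcano_data(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, .data$neg_log10_adj_p,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-object$lfc_cut, object$lfc_cut),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "log2 fold change vs GSD",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Plot a miRNA-target regulatory network
#'
#' miRNAs are round, genes square; size encodes regulatory influence and
#' colour the (inferred) direction, red up / green down.
#'
#' @param object a `mir_network`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mir_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges[c("mirna", "target_gene")],
                                     vertices = as.data.frame(object$nodes))
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- dplyr::left_join(object$edges,
                          dplyr::select(nodes, mirna = "id", x0 = "x", y0 = "y"),
                          by = "mirna") |>
    dplyr::left_join(dplyr::select(nodes, target_gene = "id", x1 = "x", y1 = "y"),
                     by = "target_gene")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, size = .data$size,
                                     colour = .data$direction,
                                     shape = .data$kind)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$id),
                       size = 2.5, vjust = -1) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "forestgreen")) +
    ggplot2::scale_shape_manual(values = c(mirna = 16, gene = 15)) +
    ggplot2::theme_void()
}

#' Box plots of expression by clinical level
#' @param data tibble from [boxplot_data()].
#' @return a ggplot faceted by probe and variable.
#' @export
plot_clinical_boxes <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(factor(.data$level), .data$log2_expr)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
    ggplot2::facet_grid(probe_id ~ variable, scales = "free") +
    ggplot2::labs(x = "clinical code", y = "normalized log2 expression") +
    ggplot2::theme_minimal()
}
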