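# ggplot2 views of the pipeline's result objects. Layout/aesthetics only;
# all quantitative attributes come straight from the result tables.

#' Plot an enrichment map
#'
#' Draws the map with a seeded Fruchterman-Reingold layout: node area scales
#' with set size, node colour with the enrichment score, edge width and
#' alpha with the overlap score. Components end up as visually separate
#' clusters because unconnected nodes repel.
#'
#' @param object An `enrichment_map`.
#' @param layout_seed Seed for the layout (layout only; the map itself is
#'   deterministic).
#' @param label Label nodes with their set names.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_map <- function(object, layout_seed = 42, label = TRUE, ...) {
  nodes <- object$nodes
  if (nrow(nodes) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty map") +
             ggplot2::theme_void())
  }
  g <- as_igraph(object)
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  pos <- tibble(set = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  nodes <- dplyr::left_join(nodes, pos, by = "set")
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0) {
    seg <- object$edges
    seg <- dplyr::left_join(seg, stats::setNames(pos, c("set_a", "xa", "ya")),
                            by = "set_a")
    seg <- dplyr::left_join(seg, stats::setNames(pos, c("set_b", "xb", "yb")),
                            by = "set_b")
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   linewidth = .data$overlap_score, alpha = .data$overlap_score),
      colour = "grey40"
    ) +
      ggplot2::scale_linewidth(range = c(0.3, 2), limits = c(0, 1)) +
      ggplot2::scale_alpha(range = c(0.3, 0.9), limits = c(0, 1))
  }
  p <- p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$size,
                 colour = .data$score)
  ) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_colour_viridis_c(name = "-log10(p)") +
    ggplot2::theme_void() +
    ggplot2::labs(size = "gene members")
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$set),
      size = 2.5, vjust = -1.2
    )
  }
  p
}

#' Plot clustered response profiles
#'
#' Scatter of the first two standardized profile dimensions, coloured by
#' cluster, with centroids marked.
#'
#' @param object A `profile_clusters` object.
#' @param dims Two profile dimensions to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_clusters <- function(object, dims = c(1, 2), ...) {
  stopifnot(length(dims) == 2, max(dims) <= ncol(object$data))
  d <- tibble(x = object$data[, dims[1]], y = object$data[, dims[2]],
              cluster = factor(object$assignment$cluster))
  cen <- tibble(x = object$centers[, dims[1]], y = object$centers[, dims[2]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(data = cen, ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = colnames(object$data)[dims[1]],
                  y = colnames(object$data)[dims[2]]) +
    ggplot2::theme_minimal()
}

#' Signal-to-noise heatmap of response profiles
#'
#' Tile heatmap of the per-gene signal-to-noise ratios under the two
#' stimuli, genes ordered by cluster (when given) and trainer SNR — the
#' standard at-a-glance view of a trainer-biased response.
#'
#' @param profiles Tibble from [response_profiles()].
#' @param clusters Optional `profile_clusters` or tibble (`gene`,
#'   `cluster`) used to order and facet genes.
#' @return A ggplot object.
#' @export
plot_snr_heatmap <- function(profiles, clusters = NULL) {
  stopifnot(all(c("gene", "snr_trainer", "snr_comparator") %in% names(profiles)))
  d <- profiles[, c("gene", "snr_trainer", "snr_comparator")]
  if (!is.null(clusters)) {
    if (inherits(clusters, "profile_clusters")) clusters <- clusters$assignment
    d <- dplyr::left_join(d, clusters, by = "gene")
  } else {
    d$cluster <- 1L
  }
  d <- dplyr::arrange(d, .data$cluster, .data$snr_trainer)
  d$gene <- factor(d$gene, levels = d$gene)
  long <- tidyr::pivot_longer(d, c("snr_trainer", "snr_comparator"),
                              names_to = "stimulus", values_to = "snr")
  long$stimulus <- sub("^snr_", "", long$stimulus)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stimulus, y = .data$gene,
                                     fill = .data$snr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster),
                        scales = "free_y", space = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "gene", fill = "signal:noise")
}
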