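#' Plot PCA scores
#'
#' @param object a `lipidome_pca`.
#' @param colour_by metadata column mapped to colour (default `"group"` when
#'   present).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lipidome_pca <- function(object, colour_by = "group", ...) {
  df <- object$scores
  pct <- round(100 * object$explained_variance_ratio[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (colour_by %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data[[colour_by]])
  }
  p +
    ggplot2::geom_point(size = 2.5, alpha = 0.85) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", pct[1]),
      y = sprintf("PC2 (%.1f%%)", pct[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Z-score clustered class heatmap
#'
#' Rows and columns follow the dendrogram orders; Z values are clipped to
#' +/- 3 SD for display only (the clustering itself used unclipped values).
#'
#' @param object a `lipidome_heatmap` from [zscore_cluster()].
#' @param clip display clipping bound in SD units (default 3).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lipidome_heatmap <- function(object, clip = 3, ...) {
  df <- tibble::as_tibble(as.data.frame(object$Z))
  df$lipid_class <- rownames(object$Z)
  long <- tidyr::pivot_longer(df, -"lipid_class", names_to = "sample_id",
                              values_to = "z")
  long$z <- pmax(pmin(long$z, clip), -clip)
  long$lipid_class <- factor(long$lipid_class, levels = object$row_order)
  long$sample_id <- factor(long$sample_id, levels = object$col_order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$lipid_class,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-clip, clip),
                                  name = "Z (SD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot a molecular network
#'
#' Force-directed layout (deterministic seed); node size encodes mean
#' relative abundance, colour the lipid class when annotations are given.
#'
#' @param net a `molecular_network`.
#' @param annotations optional annotation tibble (`feature_id`,
#'   `lipid_class`).
#' @param seed layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, annotations = NULL, seed = 1L) {
  g <- network_graph(net$nodes$feature_id, net$edges)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  layout <- igraph::layout_with_fr(g)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  nodes <- net$nodes
  nodes$x <- layout[, 1]
  nodes$y <- layout[, 2]
  if (!is.null(annotations)) {
    nodes <- dplyr::left_join(
      nodes, annotations[, c("feature_id", "lipid_class")], by = "feature_id"
    )
  }
  seg <- dplyr::left_join(
    net$edges, nodes[, c("feature_id", "x", "y")],
    by = c(feature_a = "feature_id")
  ) |>
    dplyr::left_join(nodes[, c("feature_id", "x", "y")],
                     by = c(feature_b = "feature_id"),
                     suffix = c("", "_b"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_b, yend = .data$y_b,
                   linewidth = .data$cosine),
      colour = "grey70"
    ) +
    ggplot2::scale_linewidth(range = c(0.1, 0.8), guide = "none") +
    ggplot2::theme_void()
  if ("lipid_class" %in% names(nodes)) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$mean_rel_abundance,
                                         colour = .data$lipid_class))
  } else {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$mean_rel_abundance))
  }
}

#' Plot UpSet-style intersection counts
#'
#' Bar panel of pattern counts over a dot-matrix of group membership.
#'
#' @param counts tibble from [upset_counts()].
#' @param groups optional group ordering for the matrix rows.
#' @return A ggplot object.
#' @export
plot_upset <- function(counts, groups = NULL) {
  counts <- dplyr::arrange(counts, dplyr::desc(.data$n))
  counts$pattern <- factor(counts$pattern, levels = counts$pattern)
  membership <- purrr::map2_dfr(
    counts$pattern, strsplit(as.character(counts$pattern), "&", fixed = TRUE),
    ~ tibble::tibble(pattern = .x, group = .y)
  )
  groups <- groups %||% unique(membership$group)
  membership$group <- factor(membership$group, levels = rev(groups))
  bars <- ggplot2::ggplot(counts,
                          ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "lipid species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  dots <- ggplot2::ggplot(membership,
                          ggplot2::aes(x = .data$pattern, y = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pattern)) +
    ggplot2::scale_x_discrete(limits = levels(counts$pattern)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  patchwork::wrap_plots(bars, dots, ncol = 1, heights = c(3, 1))
}

#' Plot diversity and specialization with replicate error bars
#'
#' @param summary a tibble from [replicate_errorbars()].
#' @param index `"H"` or `"delta"`.
#' @return A ggplot object.
#' @export
plot_infotheory <- function(summary, index = c("H", "delta")) {
  index <- match.arg(index)
  mean_col <- paste0(index, "_mean")
  sd_col <- paste0(index, "_sd")
  x <- if ("timepoint_h" %in% names(summary)) "timepoint_h" else "group"
  ggplot2::ggplot(summary, ggplot2::aes(x = .data[[x]],
                                        y = .data[[mean_col]],
                                        colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[mean_col]] - .data[[sd_col]],
                   ymax = .data[[mean_col]] + .data[[sd_col]]),
      width = 0.2
    ) +
    ggplot2::labs(y = if (index == "H") "lipidome diversity H (bits)" else
      "lipidome specialization δ (bits)") +
    ggplot2::theme_minimal()
}
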