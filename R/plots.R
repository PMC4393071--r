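#' Plot a persistence barcode
#'
#' Horizontal bars from birth to death radius, one per size-constrained
#' component; infinite bars are drawn to the maximum pairwise radius and
#' marked with an arrowhead-free dashed cap.
#'
#' @param object A `topo_barcode`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topo_barcode
#' @export
autoplot.topo_barcode <- function(object, ...) {
  df <- tibble::as_tibble(object[c("component_id", "birth", "death", "size")])
  df$death_plot <- ifelse(is.finite(df$death), df$death, attr(object, "max_radius"))
  df$infinite <- !is.finite(df$death)
  df$bar <- factor(seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$bar)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$birth, xend = .data$death_plot,
                   yend = .data$bar, linetype = .data$infinite),
      linewidth = 1.2
    ) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = expression(r[c]), y = NULL,
                  title = sprintf("Component barcode (n_min = %d)",
                                  attr(object, "n_min"))) +
    ggplot2::theme_minimal()
}

#' Plot a sigma ranking curve
#'
#' Ascending nondimensionalized standard deviation against rank; the left
#' tail of abnormally small values flags candidate bimodal genes. Optionally
#' highlights a gene set (e.g. planted markers or an excluded confounder
#' block).
#'
#' @param ranking Tibble from [sigma_ranking()].
#' @param highlight Optional character vector of gene ids to color.
#' @return A ggplot object.
#' @export
plot_sigma_ranking <- function(ranking, highlight = NULL) {
  df <- dplyr::filter(ranking, .data$defined)
  df$highlighted <- df$gene_id %in% highlight
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$sigma)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$highlighted), size = 0.8) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                guide = if (is.null(highlight)) "none" else "legend") +
    ggplot2::labs(x = "rank", y = expression(sigma),
                  title = "Nondimensionalized standard deviation, ascending") +
    ggplot2::theme_minimal()
  p
}

#' Plot an ordered panel-by-core heat map
#'
#' @param object A `topo_heatmap` from [heatmap_order()].
#' @param ... Unused.
#' @return A ggplot object with panel and core-group boundaries marked.
#' @method autoplot topo_heatmap
#' @export
autoplot.topo_heatmap <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -c("gene_id", "panel"),
                              names_to = "sample_id", values_to = "value")
  gene_levels <- rev(object$gene_id)
  sample_levels <- setdiff(names(object), c("gene_id", "panel"))
  long$gene_id <- factor(long$gene_id, levels = gene_levels)
  long$sample_id <- factor(long$sample_id, levels = sample_levels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green3", mid = "black", high = "red") +
    ggplot2::geom_vline(xintercept = attr(object, "n_samples_1") + 0.5,
                        color = "blue") +
    ggplot2::geom_hline(yintercept = length(gene_levels) -
                          attr(object, "n_genes_1") + 0.5,
                        color = "blue") +
    ggplot2::labs(x = "samples (join order)", y = "panel genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
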