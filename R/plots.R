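#' Plot a PCA sample embedding
#'
#' @param object A [pca_embed()] result.
#' @param colour Optional vector (same order as samples) mapped to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sample_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$group <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(
      if (is.null(colour)) NULL else ggplot2::aes(colour = .data$group),
      size = 3
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot methylation change against expression change
#'
#' @param object A [methylation_expression_correlation()] result.
#' @param ... Unused.
#' @return A ggplot of promoter methylation delta versus expression log2
#'   fold change, annotated with Spearman rho.
#' @export
autoplot.meth_expr_cor <- function(object, ...) {
  ggplot2::ggplot(object$genes,
                  ggplot2::aes(x = .data$delta, y = .data$lfc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "promoter methylation difference (fraction)",
      y = "expression log2 fold change",
      title = sprintf("Spearman rho = %.2f (permutation p = %.2g, n = %d)",
                      object$rho, object$p, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot LM/PM/HM class composition per sample
#'
#' @param class_counts The `class_counts` tibble from [class_dynamics()].
#' @return A stacked-bar ggplot of class proportions per sample.
#' @export
plot_class_composition <- function(class_counts) {
  ggplot2::ggplot(class_counts,
                  ggplot2::aes(x = .data$sample_id, y = .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(
      values = c(LM = "#4575b4", PM = "#fee090", HM = "#d73027")
    ) +
    ggplot2::labs(x = NULL, y = "fraction of CpGs", fill = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the DMC breakdown by genomic category
#'
#' Bars show hyper- and hypomethylated significant DMC counts per genomic
#' category; the hyper:hypo ratio is printed above each pair.
#'
#' @param breakdown Tibble from [dmc_category_breakdown()].
#' @return A ggplot.
#' @export
plot_dmc_breakdown <- function(breakdown) {
  long <- tidyr::pivot_longer(breakdown, c("n_hyper", "n_hypo"),
                              names_to = "direction", values_to = "n") %>%
    mutate(direction = sub("n_", "", .data$direction))
  lab <- mutate(breakdown, lab = if_else(
    is.finite(.data$ratio), sprintf("%.1f", .data$ratio), "-"
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(x = .data$category, label = .data$lab,
                   y = pmax(.data$n_hyper, .data$n_hypo)),
      inherit.aes = FALSE, vjust = -0.5, size = 3
    ) +
    ggplot2::scale_fill_manual(
      values = c(hyper = "#d73027", hypo = "#1a9850")
    ) +
    ggplot2::labs(x = NULL, y = "significant DMCs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sample dendrogram
#'
#' @param clustering A [hierarchical_cluster()] result.
#' @return A base-graphics dendrogram (invisible NULL); provided for quick
#'   inspection of the merge order.
#' @export
plot_dendrogram <- function(clustering) {
  plot(clustering$tree, xlab = "", sub = "",
       main = sprintf("average linkage, %s distance", clustering$distance))
  invisible(NULL)
}
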