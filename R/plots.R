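# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An `mdn_roc` result from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mdn_roc
#' @export
autoplot.mdn_roc <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(
    curve,
    ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(colour = "#2171b5") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot degree distributions of the bipartite network
#'
#' @param object An `mdn_bipartite`.
#' @param ... Unused.
#' @return A ggplot with one panel per side.
#' @method autoplot mdn_bipartite
#' @export
autoplot.mdn_bipartite <- function(object, ...) {
  deg <- bipartite_degrees(object)
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar(fill = "#2171b5") +
    ggplot2::facet_wrap(~side, scales = "free") +
    ggplot2::labs(
      x = "Degree in the miRNA-disease network", y = "Nodes",
      title = sprintf(
        "Degree distributions (p < %s)", format(attr(object, "threshold"))
      )
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the clustered incidence matrix
#'
#' Draws the binary miRNA-disease incidence matrix with rows and columns in
#' dendrogram order, the view in which co-regulated modules appear as
#' contiguous blocks.
#'
#' @param net An `mdn_bipartite`.
#' @param modules Optional `mdn_modules` result; when given, its dendrogram
#'   orders are reused, otherwise the clustering is computed.
#' @return A ggplot.
#' @export
plot_incidence <- function(net, modules = NULL) {
  if (is.null(modules)) {
    modules <- cluster_bipartite(net)
  }
  mat <- incidence_matrix(net)
  ord_d <- attr(modules, "hclust_diseases")$order
  ord_m <- attr(modules, "hclust_mirnas")$order
  df <- tibble::as_tibble(as.table(mat[ord_d, ord_m, drop = FALSE]),
    .name_repair = ~ c("disease_id", "mirna_id", "edge")
  ) |>
    dplyr::mutate(
      disease_id = factor(.data$disease_id, levels = rownames(mat)[ord_d]),
      mirna_id = factor(.data$mirna_id, levels = colnames(mat)[ord_m])
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$mirna_id, y = .data$disease_id, fill = factor(.data$edge))
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey95", `1` = "#cb181d"), guide = "none"
    ) +
    ggplot2::labs(x = "miRNA", y = "Disease") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6),
      axis.text.y = ggplot2::element_text(size = 6)
    )
}
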