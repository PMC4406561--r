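#' Stacked bar plot of mapping statistics
#'
#' One bar per sample, partitioned into uniquely mapped, multi-mapped,
#' unmapped and filtered reads.
#'
#' @param stats Tibble from [mapping_stats()].
#' @return A ggplot object.
#' @export
plot_mapping_stats <- function(stats) {
  long <- stats %>%
    dplyr::select("sample_id", "n_unique", "n_multi", "n_failed", "n_filtered") %>%
    tidyr::pivot_longer(-"sample_id", names_to = "category",
                        values_to = "reads") %>%
    dplyr::mutate(category = factor(.data$category,
                                    levels = c("n_unique", "n_multi",
                                               "n_failed", "n_filtered"),
                                    labels = c("unique", "multi", "unmapped",
                                               "filtered")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$reads,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "reads", fill = "mapping") +
    ggplot2::theme_minimal()
}

#' Bar plot of the top enriched GO terms
#'
#' Horizontal bars of -log10 enrichment p-values for the best-ranked terms,
#' faceted by ontology category.
#'
#' @param enrichment Tibble from [rank_terms()].
#' @param top_n Terms per category; default 10.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 10) {
  top <- dplyr::filter(enrichment, .data$rank <= top_n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = -log10(.data$p_value),
    y = stats::reorder(.data$term_id, -.data$rank))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$p_value, 2)),
                       hjust = -0.1, size = 3) +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL) +
    ggplot2::theme_minimal()
}

#' Expression heatmap of one regulatory module
#'
#' Genes by conditions, coloured from lowest (green) to highest (red)
#' expression, the conventional display for co-regulated module clusters.
#'
#' @param fit A `gnet_fit`.
#' @param module_id Module to plot.
#' @return A ggplot object.
#' @export
plot_module_heatmap <- function(fit, module_id = 1) {
  members <- fit$assignment$gene_id[fit$assignment$module_id == module_id]
  long <- fit$expr %>%
    dplyr::filter(.data$gene_id %in% members) %>%
    tidyr::pivot_longer(-"gene_id", names_to = "condition",
                        values_to = "expression")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$gene_id,
                                     fill = .data$expression)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "green", high = "red") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("module %d", module_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Module correlation-score overview of a module-network fit
#'
#' @param object A `gnet_fit`.
#' @param ... Unused.
#' @return A ggplot object: one bar per module, height = expression
#'   correlation score, labelled with module size.
#' @export
autoplot.gnet_fit <- function(object, ...) {
  ggplot2::ggplot(object$modules,
                  ggplot2::aes(x = factor(.data$module_id),
                               y = .data$correlation_score)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_genes), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = "module", y = "expression correlation score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
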