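#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_hline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression result
#'
#' @param object A `myb_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot myb_de
#' @export
autoplot.myb_de <- function(object, ...) {
  t <- object$table
  ggplot(t, aes(x = .data$log2fc, y = -log10(pmax(.data$adj_p, 1e-300)),
                colour = .data$significant)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    labs(x = "log2 fold change", y = "-log10 adjusted p",
         title = paste(object$groups[2], "vs", object$groups[1]),
         colour = "significant") +
    theme_minimal()
}

#' Column-conservation bar plot
#'
#' @param object A `conservation_profile`.
#' @param ... Unused.
#' @return A ggplot of modal residue frequency per column with the
#'   conservation threshold marked.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$position, y = .data$modal_freq,
                           fill = .data$conserved)) +
    geom_col() +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    labs(x = "alignment column", y = "modal residue frequency") +
    theme_minimal()
}

#' Cluster-profile plot of a co-expression clustering
#'
#' @param object A `coexpression_clustering`.
#' @param ... Unused.
#' @return A ggplot of per-gene log-expression profiles faceted by cluster.
#' @method autoplot coexpression_clustering
#' @export
autoplot.coexpression_clustering <- function(object, ...) {
  long <- as_tibble(object$log_expr, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "sample",
                        values_to = "log_expr") %>%
    left_join(object$table, by = "gene_id") %>%
    mutate(sample = factor(.data$sample, levels = colnames(object$log_expr)))
  ggplot(long, aes(x = .data$sample, y = .data$log_expr,
                   group = .data$gene_id)) +
    geom_line(alpha = 0.3) +
    facet_wrap(~cluster) +
    labs(x = NULL, y = "log2(FPKM + 1)") +
    theme_minimal()
}

#' Anchor-spacing histogram plot
#'
#' @param spacing_stats Output of [anchor_spacing_stats()].
#' @return A ggplot bar chart of anchor spacings per anchor pair.
#' @export
plot_anchor_spacings <- function(spacing_stats) {
  ggplot(spacing_stats, aes(x = .data$spacing, y = .data$n)) +
    geom_col() +
    facet_wrap(~anchor_pair) +
    labs(x = "anchor spacing (aa)", y = "repeats") +
    theme_minimal()
}
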