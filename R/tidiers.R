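#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x A `myb_de` object from [differential_expression()].
#' @param ... Unused.
#' @return The per-gene tibble: `gene_id`, `log2fc`, `p`, `adj_p`,
#'   `significant`.
#' @method tidy myb_de
#' @export
tidy.myb_de <- function(x, ...) x$table

#' One-row summary of a differential-expression result
#'
#' @param x A `myb_de` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_significant`, `n_up`, `n_down`,
#'   `alpha`, `fc_min`.
#' @method glance myb_de
#' @export
glance.myb_de <- function(x, ...) {
  t <- x$table
  tibble(n_genes = nrow(t),
         n_significant = sum(t$significant),
         n_up = sum(t$significant & t$log2fc > 0),
         n_down = sum(t$significant & t$log2fc < 0),
         alpha = x$alpha, fc_min = x$fc_min)
}

#' Tidy a co-expression clustering
#'
#' @param x A `coexpression_clustering` from [coexpression_clusters()].
#' @param ... Unused.
#' @return A tibble: `gene_id`, `cluster` (0 = constant profiles).
#' @method tidy coexpression_clustering
#' @export
tidy.coexpression_clustering <- function(x, ...) x$table

#' One-row summary of a co-expression clustering
#'
#' @param x A `coexpression_clustering`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_clusters`, `n_constant`.
#' @method glance coexpression_clustering
#' @export
glance.coexpression_clustering <- function(x, ...) {
  tibble(n_genes = nrow(x$table),
         n_clusters = length(setdiff(unique(x$table$cluster), 0L)),
         n_constant = sum(x$table$cluster == 0L))
}

#' Tidy a conservation profile
#'
#' @param x A `conservation_profile` from [build_conservation_profile()].
#' @param ... Unused.
#' @return The per-column tibble with a `conserved` flag at the profile's
#'   threshold.
#' @method tidy conservation_profile
#' @export
tidy.conservation_profile <- function(x, ...) {
  x$column_stats %>%
    mutate(conserved = .data$modal_freq >= x$threshold)
}

#' One-row summary of a conservation profile
#'
#' @param x A `conservation_profile`.
#' @param ... Unused.
#' @return A one-row tibble: `n_sequences`, `n_columns`, `threshold`,
#'   `n_conserved`.
#' @method glance conservation_profile
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(n_sequences = x$n_sequences,
         n_columns = nrow(x$column_stats),
         threshold = x$threshold,
         n_conserved = x$n_conserved)
}
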