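#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Draws gene baseline means from a log-normal distribution, plants a
#' `log2fc_magnitude` fold change (random sign) on a `fraction_de` subset of
#' genes between the first and second stage, scales by per-sample sequencing
#' depths drawn log-uniformly over a +/- 3-fold range, and samples
#' negative-binomial counts at the configured dispersion (Poisson in the
#' zero-dispersion limit). Deterministic under the config seed.
#'
#' @param config A [simulation_config()]; uses `de_plantings`, `n_stages`
#'   (>= 2), `n_replicates` (>= 2) and, when `gene_ids` is `NULL`, the genome
#'   layout for the gene count.
#' @param gene_ids Optional gene identifiers (sets the number of genes).
#' @return A list with `counts` (genes x samples integer matrix), `samples`
#'   (tibble: `sample`, `stage`, `replicate`, `depth_factor`), `de_truth`
#'   (tibble: `gene_id`, `true_log2fc`; nonzero entries are the planted
#'   stage-2 vs stage-1 changes) and `gene_lengths` (named vector, bp).
#' @export
simulate_counts <- function(config = simulation_config(), gene_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_stages < 2) stop("need at least 2 stages", call. = FALSE)
  if (config$n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  de <- config$de_plantings
  if (de$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%03d",
                        seq_len(config$n_chromosomes *
                                config$genes_per_chromosome))
  }
  n_genes <- length(gene_ids)
  stages <- c("EG", "MG", "Br", sprintf("S%d", seq_len(max(0, config$n_stages - 3)) + 3))
  stages <- stages[seq_len(config$n_stages)]
  samples <- tidyr::expand_grid(stage = stages,
                                replicate = seq_len(config$n_replicates)) %>%
    mutate(sample = paste0(.data$stage, "_", .data$replicate))
  with_stream(config$seed, "counts", {
    base_mean <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1.2)
    n_de <- round(de$fraction_de * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    true_lfc <- numeric(n_genes)
    if (n_de > 0) {
      true_lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        de$log2fc_magnitude
    }
    depth <- exp(runif(nrow(samples), -log(3), log(3)))
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(gene_ids, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- base_mean * depth[j]
      if (samples$stage[j] == stages[2]) mu <- mu * 2^true_lfc
      counts[, j] <- if (de$dispersion == 0) {
        rpois(n_genes, mu)
      } else {
        rnbinom(n_genes, mu = mu, size = 1 / de$dispersion)
      }
    }
    list(counts = counts,
         samples = samples %>% mutate(depth_factor = depth) %>%
           select("sample", "stage", "replicate", "depth_factor"),
         de_truth = tibble(gene_id = gene_ids, true_log2fc = true_lfc),
         gene_lengths = setNames(sample(300:3000, n_genes, replace = TRUE),
                                 gene_ids))
  })
}
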