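#' TMM normalization configuration
#'
#' @param logratio_trim Two-sided trim fraction on M-values, default 0.30.
#' @param abs_expr_trim Two-sided trim fraction on A-values, default 0.05.
#' @param reference_sample `"auto"` (sample whose upper quartile of
#'   library-scaled counts is closest to the mean upper quartile) or a sample
#'   name.
#' @return A list of class `tmm_config`.
#' @export
tmm_config <- function(logratio_trim = 0.30, abs_expr_trim = 0.05,
                       reference_sample = "auto") {
  stopifnot(logratio_trim >= 0, logratio_trim < 0.5,
            abs_expr_trim >= 0, abs_expr_trim < 0.5)
  structure(list(logratio_trim = logratio_trim,
                 abs_expr_trim = abs_expr_trim,
                 reference_sample = reference_sample),
            class = "tmm_config")
}

# weighted trimmed mean of M-values of `obs` against `ref` (raw count
# vectors). Precision weights are computed on the library-scaled proportion
# scale, (1-p)/p per sample, so that rescaling a whole library leaves the
# weights -- and hence the factors -- exactly invariant.
tmm_pair_factor <- function(obs, ref, config) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  n_o <- sum(obs); n_r <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  p_o <- obs / n_o; p_r <- ref / n_r
  w <- (1 - p_o) / p_o + (1 - p_r) / p_r
  n <- length(m)
  lo_m <- floor(n * config$logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * config$abs_expr_trim) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m, ties.method = "first") >= lo_m &
    rank(m, ties.method = "first") <= hi_m &
    rank(a, ties.method = "first") >= lo_a &
    rank(a, ties.method = "first") <= hi_a
  if (!any(keep2)) return(1)
  f <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values
#' method: the reference is the sample whose 75th percentile of
#' library-scaled counts is closest to the mean such percentile; for each
#' sample, genes with a zero count in either the sample or the reference are
#' excluded, the top and bottom 30% by log-ratio (M) and 5% by average log
#' expression (A) are trimmed, and the factor is the precision-weighted mean
#' of the remaining M-values; factors are renormalized to geometric mean 1.
#'
#' @param counts Genes x samples count matrix (or data frame with `gene_id`).
#' @param config A [tmm_config()].
#' @return A tibble: `sample`, `lib_size`, `norm_factor` (geometric mean 1).
#' @export
tmm_factors <- function(counts, config = tmm_config()) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("degenerate sample with all-zero counts: ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  }
  uq <- vapply(seq_len(ncol(m)), function(j) {
    quantile(m[, j] / lib[j], 0.75, names = FALSE)
  }, numeric(1))
  ref_j <- if (identical(config$reference_sample, "auto")) {
    which.min(abs(uq - mean(uq)))
  } else {
    match(config$reference_sample, colnames(m))
  }
  if (is.na(ref_j)) stop("unknown reference sample", call. = FALSE)
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref_j) 1 else tmm_pair_factor(m[, j], m[, ref_j], config)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble(sample = colnames(m), lib_size = unname(lib), norm_factor = unname(f))
}

#' FPKM from counts, gene lengths and normalization factors
#'
#' `FPKM = count * 1e9 / (effective library size * length)` with the
#' effective library size being the raw library size times the sample's
#' normalization factor.
#'
#' @param counts Genes x samples count matrix (or data frame with `gene_id`).
#' @param gene_lengths Named numeric vector of transcript lengths (bp), or a
#'   data frame with `gene_id` and `length`.
#' @param factors Output of [tmm_factors()], or `NULL` for factors of 1.
#' @return FPKM matrix with the dimnames of `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths, factors = NULL) {
  m <- as_count_matrix(counts)
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$length, gene_lengths$gene_id)
  }
  len <- gene_lengths[rownames(m)]
  if (anyNA(len)) stop("missing gene length(s)", call. = FALSE)
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (is.null(factors)) {
    eff <- colSums(m)
  } else {
    idx <- match(colnames(m), factors$sample)
    eff <- factors$lib_size[idx] * factors$norm_factor[idx]
  }
  if (any(eff == 0)) stop("zero effective library size", call. = FALSE)
  sweep(sweep(m * 1e9, 2, eff, "/"), 1, len, "/")
}

#' Negative-binomial differential expression between two groups
#'
#' Per-gene negative-binomial likelihood-ratio test with a moment dispersion
#' estimate shrunk 50% toward the all-gene median, using TMM effective
#' library sizes as offsets. P-values are Benjamini-Hochberg adjusted, and a
#' gene is significant iff `adj_p < 0.01` and its fold change exceeds 1.5
#' (`|log2fc| > log2(1.5)`), the conventional thresholds for calling
#' stage-wise differential expression.
#'
#' @param counts Genes x samples count matrix (or data frame with `gene_id`).
#' @param groups Character/factor vector of group labels per sample (exactly
#'   two levels, each with >= 2 replicates); `log2fc` is second level over
#'   first (levels in order of first appearance).
#' @param factors Output of [tmm_factors()], or `NULL` to compute it.
#' @param alpha Adjusted-p significance threshold, default 0.01.
#' @param fc_min Fold-change threshold, default 1.5.
#' @return An object of class `myb_de`; see [tidy.myb_de()] for the per-gene
#'   table (`gene_id`, `log2fc`, `p`, `adj_p`, `significant`).
#' @export
differential_expression <- function(counts, groups, factors = NULL,
                                    alpha = 0.01, fc_min = 1.5) {
  m <- as_count_matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  levs <- unique(groups)
  if (length(levs) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  if (is.null(factors)) factors <- tmm_factors(m)
  eff <- factors$lib_size * factors$norm_factor
  s <- eff / mean(eff)  # relative effective library sizes
  grp <- factor(groups, levels = levs)
  x2 <- grp == levs[2]

  # moment dispersion, shrunk 50% toward the all-gene median
  z <- sweep(m, 2, s, "/")
  mu_hat <- rowMeans(z)
  v_within <- (apply(z[, !x2, drop = FALSE], 1, stats::var) +
               apply(z[, x2, drop = FALSE], 1, stats::var)) / 2
  phi_raw <- pmax(0, (v_within - mu_hat) / mu_hat^2)
  phi_raw[!is.finite(phi_raw)] <- 0
  phi_med <- median(phi_raw[mu_hat > 0])
  phi <- 0.5 * phi_raw + 0.5 * phi_med

  off <- log(s)
  x_null <- matrix(1, ncol(m), 1)
  x_alt <- cbind(1, as.numeric(x2))
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    m1 <- mean(y[!x2] / s[!x2]); m2 <- mean(y[x2] / s[x2])
    lfc <- log2((m2 + 0.5) / (m1 + 0.5))
    if (all(y == 0)) {
      return(tibble(gene_id = rownames(m)[i], log2fc = 0, p = 1))
    }
    fam <- if (phi[i] < 1e-8) poisson() else
      MASS::negative.binomial(theta = 1 / phi[i])
    fit1 <- suppressWarnings(stats::glm.fit(x_alt, y, family = fam,
                                            offset = off))
    fit0 <- suppressWarnings(stats::glm.fit(x_null, y, family = fam,
                                            offset = off))
    lrt <- max(0, fit0$deviance - fit1$deviance)
    tibble(gene_id = rownames(m)[i], log2fc = lfc,
           p = pchisq(lrt, df = 1, lower.tail = FALSE))
  })
  res <- res %>% mutate(
    adj_p = p.adjust(.data$p, method = "BH"),
    significant = .data$adj_p < alpha & abs(.data$log2fc) > log2(fc_min))
  structure(list(table = res, groups = levs, alpha = alpha, fc_min = fc_min,
                 dispersion = tibble(gene_id = rownames(m), phi_raw = phi_raw,
                                     phi = phi)),
            class = "myb_de")
}

#' @export
print.myb_de <- function(x, ...) {
  cat("Differential expression:", x$groups[2], "vs", x$groups[1], "--",
      nrow(x$table), "genes,", sum(x$table$significant), "significant",
      sprintf("(adj p < %g, FC > %g)\n", x$alpha, x$fc_min))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Averages replicate Ct values per gene and condition, forms
#' `dCt = Ct_target - Ct_reference`, subtracts the calibrator condition's
#' mean dCt (`ddCt`), and reports `2^-ddCt`. A two-sided two-sample t-test on
#' the replicate dCt values of each condition against the calibrator gives a
#' p-value per gene and condition.
#'
#' @param measurements Data frame with columns `gene`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param calibrator Condition used as calibrator (its own relative
#'   expression is 1 by construction).
#' @return A tibble: `gene`, `condition`, `mean_dct`, `ddct`,
#'   `relative_expression`, `p` (`NA` for the calibrator itself).
#' @export
delta_delta_ct <- function(measurements, calibrator) {
  need <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(measurements)))
  if (anyNA(measurements$ct_reference)) {
    stop("missing reference-gene Ct value(s)", call. = FALSE)
  }
  if (!calibrator %in% measurements$condition) {
    stop("calibrator condition not present", call. = FALSE)
  }
  dat <- measurements %>%
    mutate(dct = .data$ct_target - .data$ct_reference)
  missing_cal <- setdiff(unique(dat$gene),
                         unique(dat$gene[dat$condition == calibrator]))
  if (length(missing_cal) > 0) {
    stop("calibrator missing for gene(s): ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  }
  cal <- dat %>%
    filter(.data$condition == calibrator) %>%
    group_by(.data$gene) %>%
    summarise(cal_mean = mean(.data$dct), cal_dct = list(.data$dct))
  dat %>%
    group_by(.data$gene, .data$condition) %>%
    summarise(mean_dct = mean(.data$dct), dcts = list(.data$dct),
              .groups = "drop") %>%
    left_join(cal, by = "gene") %>%
    mutate(
      ddct = .data$mean_dct - .data$cal_mean,
      relative_expression = 2^(-.data$ddct),
      p = purrr::map2_dbl(.data$dcts, .data$cal_dct, function(a, b) {
        if (identical(a, b)) return(NA_real_)
        if (length(a) < 2 || length(b) < 2 ||
            (stats::sd(a) == 0 && stats::sd(b) == 0)) return(NA_real_)
        t.test(a, b)$p.value
      })) %>%
    select("gene", "condition", "mean_dct", "ddct",
           "relative_expression", "p") %>%
    arrange(.data$gene, .data$condition)
}

#' Co-expression clustering of expression profiles
#'
#' Hierarchical average-linkage clustering on the correlation distance
#' `1 - Pearson(r)` of `log2(FPKM + 1)` profiles, cut at `k` clusters or at
#' height `h`. Genes with zero profile variance (Pearson undefined) are set
#' aside in a dedicated `"constant"` cluster (id 0) before clustering.
#'
#' @param fpkm Genes x samples FPKM matrix (or data frame with `gene_id`).
#' @param k Number of clusters (of the non-constant genes).
#' @param h Alternative cut height on the dendrogram.
#' @return An object of class `coexpression_clustering` with the assignment
#'   table (`gene_id`, `cluster`), the `hclust` tree and the log-expression
#'   matrix.
#' @export
coexpression_clusters <- function(fpkm, k = NULL, h = NULL) {
  m <- as_count_matrix(fpkm)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(k) && is.null(h)) stop("supply k or h", call. = FALSE)
  x <- log2(m + 1)
  constant <- apply(x, 1, stats::sd) == 0
  xv <- x[!constant, , drop = FALSE]
  if (!is.null(k) && nrow(xv) < k) {
    stop("fewer variable genes than clusters", call. = FALSE)
  }
  if (nrow(xv) < 2) stop("need at least 2 variable profiles", call. = FALSE)
  d <- as.dist(1 - cor(t(xv)))
  tree <- hclust(d, method = "average")
  assign <- if (!is.null(k)) cutree(tree, k = k) else cutree(tree, h = h)
  table <- dplyr::bind_rows(
    tibble(gene_id = rownames(xv), cluster = as.integer(assign)),
    tibble(gene_id = rownames(x)[constant], cluster = 0L)) %>%
    arrange(match(.data$gene_id, rownames(x)))
  structure(list(table = table, tree = tree, log_expr = x,
                 k = k, h = h),
            class = "coexpression_clustering")
}

#' @export
print.coexpression_clustering <- function(x, ...) {
  n_const <- sum(x$table$cluster == 0L)
  cat("Co-expression clustering:", nrow(x$table), "genes in",
      length(setdiff(unique(x$table$cluster), 0L)), "cluster(s)",
      if (n_const > 0) paste0("(+", n_const, " constant)"), "\n")
  invisible(x)
}
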