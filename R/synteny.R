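#' Synteny chaining configuration
#'
#' @param min_anchors Minimum anchors per reported segment, default 5.
#' @param max_rank_gap Maximum rank gap (gene positions skipped) between
#'   consecutive chain members, in both genomes, default 25.
#' @param gap_penalty Score penalty per skipped rank; chain score is
#'   `anchors - gap_penalty * gaps`. Default 0.05.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(min_anchors = 5L, max_rank_gap = 25L,
                         gap_penalty = 0.05) {
  stopifnot(min_anchors >= 2, max_rank_gap >= 1, gap_penalty >= 0)
  structure(list(min_anchors = as.integer(min_anchors),
                 max_rank_gap = as.integer(max_rank_gap),
                 gap_penalty = gap_penalty),
            class = "chain_config")
}

#' Build homolog anchors from gene orders
#'
#' Assigns each gene its ordinal rank along its chromosome (by start
#' coordinate) in both genomes and emits one anchor per homolog pair.
#' Consecutive genes of one genome hitting the same partner gene (tandem
#' arrays) are collapsed to the best-scoring anchor before chaining, the
#' standard collinearity practice.
#'
#' @param homolog_pairs Data frame with columns `gene_a`, `gene_b` and
#'   optionally `score` (used for tandem-array collapse; defaults to 0).
#' @param gene_models_a,gene_models_b Gene-model tables of the two genomes.
#' @return A tibble: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `rank_a`,
#'   `rank_b`, `start_a`, `end_a`, `start_b`, `end_b`, `score`.
#' @export
build_anchors <- function(homolog_pairs, gene_models_a, gene_models_b) {
  if (nrow(homolog_pairs) == 0) return(empty_anchor_table())
  rank_table <- function(gm, suffix) {
    gm %>%
      arrange(.data$chromosome, .data$start) %>%
      group_by(.data$chromosome) %>%
      mutate(rank = row_number() - 1L) %>%
      ungroup() %>%
      select(gene_id = "gene_id", chrom = "chromosome",
             rank = "rank", start = "start", end = "end") %>%
      stats::setNames(paste0(names(.), "_", suffix))
  }
  ra <- rank_table(gene_models_a, "a")
  rb <- rank_table(gene_models_b, "b")
  pairs <- homolog_pairs
  if (!"score" %in% names(pairs)) pairs$score <- 0
  missing_a <- setdiff(pairs$gene_a, ra$gene_id_a)
  missing_b <- setdiff(pairs$gene_b, rb$gene_id_b)
  if (length(missing_a) + length(missing_b) > 0) {
    stop("unplaced gene(s) in homolog pairs: ",
         paste(c(missing_a, missing_b), collapse = ", "), call. = FALSE)
  }
  anchors <- pairs %>%
    left_join(ra, by = c(gene_a = "gene_id_a")) %>%
    left_join(rb, by = c(gene_b = "gene_id_b")) %>%
    select("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b",
           "start_a", "end_a", "start_b", "end_b", "score")
  # tandem-array collapse: runs of consecutive ranks in one genome hitting
  # the same partner gene keep only the best-scoring member
  collapse_runs <- function(df, rank_col, partner_col) {
    df %>%
      arrange(.data$chrom_a, .data$chrom_b, .data[[rank_col]]) %>%
      group_by(.data$chrom_a, .data$chrom_b) %>%
      mutate(.run = cumsum(
        .data[[partner_col]] != dplyr::lag(.data[[partner_col]],
                                           default = "") |
        .data[[rank_col]] != dplyr::lag(.data[[rank_col]],
                                        default = -2L) + 1L)) %>%
      group_by(.data$chrom_a, .data$chrom_b, .data$.run) %>%
      slice(which.max(.data$score)) %>%
      ungroup() %>%
      select(-".run")
  }
  anchors <- collapse_runs(anchors, "rank_a", "gene_b")
  anchors <- collapse_runs(anchors, "rank_b", "gene_a")
  anchors %>% arrange(.data$chrom_a, .data$chrom_b, .data$rank_a)
}

empty_anchor_table <- function() {
  tibble(gene_a = character(), gene_b = character(),
         chrom_a = character(), chrom_b = character(),
         rank_a = integer(), rank_b = integer(),
         start_a = integer(), end_a = integer(),
         start_b = integer(), end_b = integer(), score = numeric())
}

# best chain by DP over rank_a-sorted anchors in one orientation;
# returns list(score, idx) or NULL
best_chain_dp <- function(sub, orientation, config) {
  n <- nrow(sub)
  if (n == 0) return(NULL)
  score <- rep(1, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      da <- sub$rank_a[i] - sub$rank_a[j]
      db <- if (orientation == "forward") sub$rank_b[i] - sub$rank_b[j]
            else sub$rank_b[j] - sub$rank_b[i]
      if (da < 1 || db < 1) next
      if (da > config$max_rank_gap || db > config$max_rank_gap) next
      cand <- score[j] + 1 - config$gap_penalty * ((da - 1) + (db - 1))
      if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
    }
  }
  best <- which.max(score)
  idx <- integer(0)
  i <- best
  while (!is.na(i)) { idx <- c(i, idx); i <- prev[i] }
  list(score = score[best], idx = idx, orientation = orientation)
}

#' Chain homolog anchors into conserved syntenic segments
#'
#' Within each chromosome pair, maximal-score chains of anchors are found by
#' dynamic programming over rank-sorted anchors, separately for forward
#' (both ranks strictly increasing) and reversed (rank_b strictly
#' decreasing) orientations, with consecutive members at most `max_rank_gap`
#' ranks apart in both genomes. Chains are extracted best score first, each
#' anchor joining at most one segment; chains below `min_anchors` are
#' dropped.
#'
#' @param anchors Anchor table from [build_anchors()] (or any table with
#'   `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `rank_a`, `rank_b`).
#' @param config A [chain_config()].
#' @return A tibble of segments: `segment_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, `score`, span columns (`NA` when the
#'   anchors carry no coordinates) and an `anchors` list-column of member
#'   anchor tables.
#' @export
chain_anchors <- function(anchors, config = chain_config()) {
  stopifnot(all(c("gene_a", "gene_b", "chrom_a", "chrom_b",
                  "rank_a", "rank_b") %in% names(anchors)))
  segs <- list()
  for (key in unique(paste(anchors$chrom_a, "\r", anchors$chrom_b))) {
    sub <- anchors %>%
      filter(paste(.data$chrom_a, "\r", .data$chrom_b) == key) %>%
      arrange(.data$rank_a, .data$rank_b)
    repeat {
      if (nrow(sub) < config$min_anchors) break
      fwd <- best_chain_dp(sub, "forward", config)
      rev_ <- best_chain_dp(sub, "reversed", config)
      cand <- list(fwd, rev_)
      cand <- cand[!vapply(cand, is.null, logical(1))]
      cand <- cand[vapply(cand, function(x) length(x$idx), integer(1)) >=
                     config$min_anchors]
      if (length(cand) == 0) break
      best <- cand[[which.max(vapply(cand, function(x) x$score, numeric(1)))]]
      members <- sub[best$idx, ]
      has_span <- all(c("start_a", "end_a", "start_b", "end_b") %in%
                        names(members))
      segs[[length(segs) + 1]] <- tibble(
        chrom_a = members$chrom_a[1], chrom_b = members$chrom_b[1],
        orientation = best$orientation,
        n_anchors = nrow(members), score = best$score,
        span_a_start = if (has_span) min(members$start_a) else NA_integer_,
        span_a_end = if (has_span) max(members$end_a) else NA_integer_,
        span_b_start = if (has_span) min(members$start_b) else NA_integer_,
        span_b_end = if (has_span) max(members$end_b) else NA_integer_,
        anchors = list(members))
      sub <- sub[-best$idx, ]
    }
  }
  if (length(segs) == 0) {
    return(tibble(segment_id = integer(), chrom_a = character(),
                  chrom_b = character(), orientation = character(),
                  n_anchors = integer(), score = numeric(),
                  span_a_start = integer(), span_a_end = integer(),
                  span_b_start = integer(), span_b_end = integer(),
                  anchors = list()))
  }
  dplyr::bind_rows(segs) %>%
    arrange(desc(.data$score)) %>%
    mutate(segment_id = row_number()) %>%
    select("segment_id", dplyr::everything())
}

#' Summarize syntenic segments with respect to a gene family
#'
#' Produces the segment-level family statistics: how many segments contain at
#' least one family gene, how many of those lie on non-matching chromosome
#' labels or run in reversed gene order, how many distinct family genes fall
#' inside segments, and the per-chromosome collinear family-gene counts.
#'
#' @param segments Output of [chain_anchors()].
#' @param family_gene_ids Character vector of family gene ids (matched
#'   against `gene_a` of the anchors).
#' @param chrom_map Optional named character vector mapping each `chrom_a`
#'   label to its corresponding `chrom_b` label; segments whose `chrom_b`
#'   differs from `chrom_map[chrom_a]` count as "different chromosome".
#'   Defaults to the identity mapping.
#' @return A list with `summary` (one-row tibble: `n_segments`,
#'   `n_family_segments`, `n_diff_chromosome`, `n_reversed`,
#'   `n_family_genes_in_segments`) and `per_chromosome` (tibble: `chrom_a`,
#'   `n_family_genes`).
#' @export
summarize_segments <- function(segments, family_gene_ids, chrom_map = NULL) {
  if (nrow(segments) == 0) {
    return(list(summary = tibble(n_segments = 0L, n_family_segments = 0L,
                                 n_diff_chromosome = 0L, n_reversed = 0L,
                                 n_family_genes_in_segments = 0L),
                per_chromosome = tibble(chrom_a = character(),
                                        n_family_genes = integer())))
  }
  seg_family <- purrr::map_lgl(segments$anchors, function(a) {
    any(a$gene_a %in% family_gene_ids)
  })
  expected_b <- if (is.null(chrom_map)) segments$chrom_a
                else unname(chrom_map[segments$chrom_a])
  fam <- segments[seg_family, ]
  fam_expected_b <- expected_b[seg_family]
  fam_genes <- unique(unlist(purrr::map(fam$anchors, function(a) {
    intersect(a$gene_a, family_gene_ids)
  })))
  per_chr <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    a <- segments$anchors[[i]]
    tibble(chrom_a = segments$chrom_a[i],
           gene = intersect(a$gene_a, family_gene_ids))
  }) %>%
    distinct(.data$chrom_a, .data$gene) %>%
    dplyr::count(.data$chrom_a, name = "n_family_genes")
  list(
    summary = tibble(
      n_segments = nrow(segments),
      n_family_segments = sum(seg_family),
      n_diff_chromosome = sum(fam$chrom_b != fam_expected_b),
      n_reversed = sum(fam$orientation == "reversed"),
      n_family_genes_in_segments = length(fam_genes)),
    per_chromosome = per_chr)
}
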