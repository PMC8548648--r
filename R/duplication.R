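#' Configuration for duplicate-pair discovery and molecular evolution
#'
#' Holds the filtering thresholds and the molecular-clock rate used throughout
#' the duplication analysis.
#'
#' @param lambda Clock-like synonymous substitution rate, substitutions per
#'   synonymous site per year. Default `6.96e-9`, the rate commonly assumed
#'   for Solanaceae nuclear genes; divergence time is `T = Ks / (2 lambda)`.
#' @param identity_min Minimum (strict) alignment identity for a duplicate
#'   pair, default 0.75.
#' @param coverage_min Minimum (strict) query coverage within one genome,
#'   default 0.75; coverage is evaluated with the shorter protein as query.
#' @param coverage_min_cross Coverage threshold for cross-genome homolog
#'   screens, default 0.80.
#' @param evalue_max E-value cutoff used when importing external homology
#'   hits, default `1e-3`.
#' @param tandem_distance Maximum same-chromosome gap (bp, strict `<`) for a
#'   tandem duplicate, default 100000.
#' @param neutral_band Two-element omega interval called neutral. The
#'   default `c(1, 1)` reproduces the strict textbook rule (omega < 1
#'   purifying, omega > 1 positive, exactly 1 neutral); widen it to treat a
#'   tolerance window around 1 as neutral.
#' @return A list of class `evol_config`.
#' @export
evol_config <- function(lambda = 6.96e-9,
                        identity_min = 0.75,
                        coverage_min = 0.75,
                        coverage_min_cross = 0.80,
                        evalue_max = 1e-3,
                        tandem_distance = 1e5,
                        neutral_band = c(1, 1)) {
  stopifnot(lambda > 0, identity_min >= 0, identity_min <= 1,
            coverage_min >= 0, coverage_min <= 1,
            length(neutral_band) == 2, neutral_band[1] <= neutral_band[2])
  structure(list(lambda = lambda, identity_min = identity_min,
                 coverage_min = coverage_min,
                 coverage_min_cross = coverage_min_cross,
                 evalue_max = evalue_max, tandem_distance = tandem_distance,
                 neutral_band = neutral_band),
            class = "evol_config")
}

#' Local protein alignment summary
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (open 11, extend 1). Identity is the proportion of identical residues over
#' aligned columns with a residue in both sequences (gap columns excluded);
#' coverage is the number of aligned residues of the query divided by the
#' query length, the query being the shorter sequence.
#'
#' @param a,b Amino-acid sequences.
#' @return A one-row tibble with `identity`, `coverage`, `score`, the gapped
#'   aligned strings `aligned_a`, `aligned_b`, and the 1-based offsets
#'   `start_a`, `end_a`, `start_b`, `end_b` of the aligned region.
#' @export
align_protein_pair <- function(a, b) {
  check_protein(a, what = "first"); check_protein(b, what = "second")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pa <- split1(as.character(Biostrings::alignedPattern(aln)))
  ps <- split1(as.character(Biostrings::alignedSubject(aln)))
  resid <- pa != "-" & ps != "-"
  identity <- if (sum(resid) == 0) 0 else mean(pa[resid] == ps[resid])
  qlen <- min(nchar(a), nchar(b))
  q_aligned <- if (nchar(a) <= nchar(b)) sum(pa != "-") else sum(ps != "-")
  tibble(
    identity = identity,
    coverage = q_aligned / qlen,
    score = Biostrings::score(aln),
    aligned_a = paste(pa, collapse = ""),
    aligned_b = paste(ps, collapse = ""),
    start_a = Biostrings::start(Biostrings::pattern(aln)),
    end_a = Biostrings::end(Biostrings::pattern(aln)),
    start_b = Biostrings::start(Biostrings::subject(aln)),
    end_b = Biostrings::end(Biostrings::subject(aln))
  )
}

#' Discover candidate duplicate gene pairs in a proteome
#'
#' Aligns all protein pairs and keeps those with identity strictly above
#' `identity_min` and coverage strictly above `coverage_min` (shorter protein
#' as query), the screen used for within-genome duplicate discovery.
#'
#' @param proteome A data frame with columns `gene_id` and `protein`, or a
#'   named character vector of protein sequences.
#' @param gene_models A data frame with columns `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`; every protein must have a gene model.
#' @param config An [evol_config()].
#' @return A tibble of candidate pairs, one per row, `gene_a < gene_b`
#'   lexicographically, ordered by (`gene_a`, `gene_b`), with alignment
#'   columns as in [align_protein_pair()].
#' @export
find_duplicate_pairs <- function(proteome, gene_models, config = evol_config()) {
  if (is.character(proteome)) {
    proteome <- tibble(gene_id = names(proteome), protein = unname(proteome))
  }
  stopifnot(all(c("gene_id", "protein") %in% names(proteome)))
  missing <- setdiff(proteome$gene_id, gene_models$gene_id)
  if (length(missing) > 0) {
    stop("no gene model for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(proteome)
  if (n < 2) return(empty_pair_table())
  idx <- utils::combn(n, 2)
  rows <- purrr::map(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    ids <- sort(c(proteome$gene_id[i], proteome$gene_id[j]))
    aln <- align_protein_pair(proteome$protein[i], proteome$protein[j])
    dplyr::bind_cols(tibble(gene_a = ids[1], gene_b = ids[2],
                            id_i = proteome$gene_id[i]), aln)
  })
  out <- dplyr::bind_rows(rows) %>%
    filter(.data$identity > config$identity_min,
           .data$coverage > config$coverage_min)
  # aligned_a always corresponds to the first *input* protein; re-key so the
  # aligned strings follow the sorted (gene_a, gene_b) order
  swap <- out$id_i != out$gene_a
  if (any(swap)) {
    tmp <- out$aligned_a[swap]
    out$aligned_a[swap] <- out$aligned_b[swap]
    out$aligned_b[swap] <- tmp
    tmp <- out$start_a[swap]
    out$start_a[swap] <- out$start_b[swap]; out$start_b[swap] <- tmp
    tmp <- out$end_a[swap]
    out$end_a[swap] <- out$end_b[swap]; out$end_b[swap] <- tmp
  }
  out %>% select(-"id_i") %>% arrange(.data$gene_a, .data$gene_b)
}

empty_pair_table <- function() {
  tibble(gene_a = character(), gene_b = character(), identity = numeric(),
         coverage = numeric(), score = numeric(), aligned_a = character(),
         aligned_b = character(), start_a = integer(), end_a = integer(),
         start_b = integer(), end_b = integer())
}

#' Classify duplicate pairs as tandem or segmental
#'
#' A pair is tandem iff both genes lie on the same chromosome and the gap
#' between their nearest span ends is strictly below the tandem distance
#' (default 100 kb); every other placement, including different chromosomes,
#' is segmental. Overlapping spans have gap 0.
#'
#' @param pairs A data frame with columns `gene_a`, `gene_b`.
#' @param gene_models Gene model table (`gene_id`, `chromosome`, `start`,
#'   `end`).
#' @param config An [evol_config()].
#' @return `pairs` with added columns `mode` (`"tandem"`/`"segmental"`) and
#'   `distance` (bp gap; `NA` across chromosomes).
#' @export
classify_duplication <- function(pairs, gene_models, config = evol_config()) {
  gm <- gene_models
  a <- gm[match(pairs$gene_a, gm$gene_id), ]
  b <- gm[match(pairs$gene_b, gm$gene_id), ]
  if (anyNA(a$gene_id) || anyNA(b$gene_id)) {
    stop("pair references a gene without a gene model", call. = FALSE)
  }
  same_chr <- a$chromosome == b$chromosome
  gap <- pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end) - 1)
  pairs %>% mutate(
    distance = ifelse(same_chr, gap, NA_real_),
    mode = ifelse(same_chr & gap < config$tandem_distance,
                  "tandem", "segmental"))
}

#' Molecular-clock divergence time from Ks
#'
#' `T = Ks / (2 lambda)`, reported in million years (MYA).
#'
#' @param ks Synonymous substitutions per synonymous site (vectorized; `NA`
#'   propagates, e.g. for saturated pairs).
#' @param config An [evol_config()] supplying `lambda`.
#' @return Divergence times in MYA.
#' @export
#' @examples
#' divergence_time(0.526)  # ~37.8 MYA at the default clock rate
divergence_time <- function(ks, config = evol_config()) {
  stopifnot(all(ks >= 0, na.rm = TRUE))
  ks / (2 * config$lambda) / 1e6
}

#' Classify selection regime from omega
#'
#' Omega inside the neutral band is neutral; below purifying; above positive;
#' `NA` stays `NA`.
#'
#' @param omega Ka/Ks ratio(s).
#' @param config An [evol_config()] supplying `neutral_band`.
#' @return Character vector in `purifying`, `neutral`, `positive`, `NA`.
#' @export
classify_selection <- function(omega, config = evol_config()) {
  lo <- config$neutral_band[1]; hi <- config$neutral_band[2]
  dplyr::case_when(
    is.na(omega) ~ NA_character_,
    omega < lo ~ "purifying",
    omega > hi ~ "positive",
    TRUE ~ "neutral")
}

#' Full duplicate-pair characterization
#'
#' Convenience pipeline over the module: discovers duplicate pairs, classifies
#' tandem/segmental, estimates NG86 Ka/Ks on the codon-aligned pairs, and adds
#' selection class and clock divergence time, producing a table shaped like a
#' gene-family duplication report (pair, mode, Ka, Ks, omega, T).
#'
#' @param proteome Data frame with `gene_id`, `protein`, `cds`.
#' @param gene_models Gene model table.
#' @param config An [evol_config()].
#' @return A tibble with one row per retained pair: `gene_a`, `gene_b`,
#'   `mode`, `distance`, `identity`, `coverage`, `Ka`, `Ks`, `omega`,
#'   `selection`, `T_mya`.
#' @export
characterize_duplicates <- function(proteome, gene_models,
                                    config = evol_config()) {
  stopifnot(all(c("gene_id", "protein", "cds") %in% names(proteome)))
  pairs <- find_duplicate_pairs(proteome, gene_models, config)
  if (nrow(pairs) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  mode = character(), distance = numeric(),
                  identity = numeric(), coverage = numeric(),
                  Ka = numeric(), Ks = numeric(), omega = numeric(),
                  selection = character(), T_mya = numeric()))
  }
  pairs <- classify_duplication(pairs, gene_models, config)
  kaks <- purrr::map(seq_len(nrow(pairs)), function(i) {
    row <- pairs[i, ]
    cds_a <- proteome$cds[match(row$gene_a, proteome$gene_id)]
    cds_b <- proteome$cds[match(row$gene_b, proteome$gene_id)]
    aln <- codon_align(row, cds_a, cds_b)
    ng86_ka_ks(aln)[, c("Ka", "Ks", "omega")]
  })
  dplyr::bind_cols(
    pairs %>% select("gene_a", "gene_b", "mode", "distance",
                     "identity", "coverage"),
    dplyr::bind_rows(kaks)
  ) %>% mutate(
    selection = classify_selection(.data$omega, config),
    T_mya = divergence_time(.data$Ks, config))
}

#' Co-localize genes with QTL intervals
#'
#' A gene is reported iff its full span lies within a QTL interval on the
#' same chromosome (containment, the reading of "located within"); with
#' `any_overlap = TRUE` a single shared base pair suffices.
#'
#' @param gene_models Gene model table (`gene_id`, `chromosome`, `start`,
#'   `end`), 1-based inclusive.
#' @param qtl_intervals Data frame with columns `chromosome`, `start`, `end`,
#'   and optionally `trait` and `qtl` (interval name).
#' @param any_overlap Relax containment to any overlap. Default `FALSE`.
#' @return A tibble with one row per (gene, QTL) co-localization.
#' @export
qtl_colocalize <- function(gene_models, qtl_intervals, any_overlap = FALSE) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(qtl_intervals)))
  unknown <- setdiff(qtl_intervals$chromosome, gene_models$chromosome)
  if (length(unknown) > 0) {
    stop("QTL on unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  qtl <- qtl_intervals %>%
    dplyr::rename(qtl_start = "start", qtl_end = "end")
  hits <- dplyr::inner_join(gene_models, qtl, by = "chromosome",
                            relationship = "many-to-many")
  if (any_overlap) {
    hits <- hits %>% filter(.data$start <= .data$qtl_end,
                            .data$end >= .data$qtl_start)
  } else {
    hits <- hits %>% filter(.data$start >= .data$qtl_start,
                            .data$end <= .data$qtl_end)
  }
  as_tibble(hits) %>% arrange(.data$chromosome, .data$start)
}
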