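#' Extract strand-aware upstream (promoter) regions
#'
#' Takes up to `length` bases immediately upstream of each gene's
#' transcription start site on the coding strand: for `+` strand genes the
#' bases before `start`, for `-` strand genes the reverse complement of the
#' bases after `end`. Regions are clipped at the chromosome boundary.
#'
#' @param gene_models Gene-model tibble (`gene_id`, `chromosome`, `start`,
#'   `end`, `strand`; 1-based inclusive).
#' @param genome Named character vector of chromosome sequences.
#' @param length Upstream length in bp, default 1500.
#' @return A tibble: `gene_id`, `sequence` (5'->3' relative to the gene),
#'   `length`, `truncated`.
#' @export
extract_upstream <- function(gene_models, genome, length = 1500) {
  missing <- setdiff(gene_models$chromosome, names(genome))
  if (length(missing) > 0) {
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  target_len <- length
  purrr::map_dfr(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, ]
    chrom <- genome[[g$chromosome]]
    if (g$strand == "+") {
      from <- max(1, g$start - target_len)
      to <- g$start - 1
      seq <- if (to < from) "" else substr(chrom, from, to)
    } else {
      from <- g$end + 1
      to <- min(nchar(chrom), g$end + target_len)
      seq <- if (to < from) "" else reverse_complement(substr(chrom, from, to))
    }
    tibble(gene_id = g$gene_id, sequence = seq, length = nchar(seq),
           truncated = nchar(seq) < target_len)
  })
}

# TRUE if the motif is period-minimal (no divisor period generates it)
is_period_minimal <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && motif == strrep(substr(motif, 1, d), p / d)) {
      return(FALSE)
    }
  }
  TRUE
}

find_ssrs_one <- function(seq, seq_id, min_motif, max_motif, min_repeats) {
  check_dna(seq, allow_n = TRUE, what = "SSR target")
  s <- split1(seq)
  L <- length(s)
  out <- list()
  for (p in min_motif:max_motif) {
    if (L < p * min_repeats) next
    eq <- s[seq_len(L - p)] == s[seq_len(L - p) + p] &
      s[seq_len(L - p)] != "N" & s[seq_len(L - p) + p] != "N"
    # maximal runs of TRUE in eq; a run of length l starting at i spans a
    # tandem region of l + p bases starting at i
    r <- rle(eq)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      i <- pos[k]
      l <- r$lengths[k]
      reps <- (l + p) %/% p
      if (reps < min_repeats) next
      motif <- substr(seq, i, i + p - 1)
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_period_minimal(motif)) next
      out[[length(out) + 1]] <- tibble(
        sequence_id = seq_id, motif = motif, repeats = reps,
        start = i, end = i + p * reps - 1)
    }
  }
  dplyr::bind_rows(out)
}

#' Find simple sequence repeats (SSRs)
#'
#' Reports all maximal perfect tandem runs whose period-minimal motif length
#' is within `[min_motif, max_motif]` and that contain at least `min_repeats`
#' full motif copies (partial trailing copies are not counted; the reported
#' locus covers full copies only). Sub-period duplicates are suppressed: an
#' `(AT)6` run is reported as AT x 6, never as ATAT x 3. Overlapping runs of
#' genuinely different periods are all reported. `N` never occurs inside a
#' reported run.
#'
#' @param sequences Named character vector of DNA sequences (or a single
#'   unnamed sequence, reported as `seq1`).
#' @param min_motif,max_motif Motif length bounds, defaults 2 and 6
#'   (mononucleotide runs are excluded by the default `min_motif = 2`).
#' @param min_repeats Minimum number of full motif copies, default 6.
#' @return A tibble: `sequence_id`, `motif` (as observed), `repeats`,
#'   `start`, `end` (1-based inclusive; `end - start + 1 = nchar(motif) *
#'   repeats`), sorted by sequence and position.
#' @export
find_ssrs <- function(sequences, min_motif = 2, max_motif = 6,
                      min_repeats = 6) {
  stopifnot(min_motif >= 1, max_motif >= min_motif, min_repeats >= 2)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  out <- purrr::imap(sequences, function(s, id) {
    find_ssrs_one(s, id, min_motif, max_motif, min_repeats)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(sequence_id = character(), motif = character(),
                  repeats = integer(), start = integer(), end = integer()))
  }
  res %>% arrange(match(.data$sequence_id, names(sequences)), .data$start,
                  .data$motif)
}

#' Scan gene bodies and upstream regions for SSRs
#'
#' Convenience wrapper reproducing the genic + 1.5-kb-upstream SSR screen:
#' runs [find_ssrs()] on every gene's genomic span (`region = "genic"`) and
#' on its upstream region (`region = "upstream"`).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gene_models Gene-model tibble.
#' @param upstream Upstream length in bp, default 1500.
#' @param ... Passed to [find_ssrs()].
#' @return [find_ssrs()] output with `sequence_id` set to the gene id and an
#'   added `region` column; positions are relative to the scanned region.
#' @export
scan_gene_ssrs <- function(genome, gene_models, upstream = 1500, ...) {
  genic <- setNames(
    vapply(seq_len(nrow(gene_models)), function(i) {
      g <- gene_models[i, ]
      s <- substr(genome[[g$chromosome]], g$start, g$end)
      if (g$strand == "-") s <- reverse_complement(s)
      s
    }, character(1)), gene_models$gene_id)
  up <- extract_upstream(gene_models, genome, length = upstream)
  up_seqs <- setNames(up$sequence, up$gene_id)
  up_seqs <- up_seqs[nchar(up_seqs) > 0]
  dplyr::bind_rows(
    find_ssrs(genic, ...) %>% mutate(region = "genic"),
    find_ssrs(up_seqs, ...) %>% mutate(region = "upstream"))
}

#' Summarize an SSR locus table
#'
#' Tallies loci by motif length (periods 2-6), reports the modal motif (ties
#' broken by the lexicographically smallest motif) and the longest locus
#' (maximal `repeats x period`).
#'
#' @param loci Output of [find_ssrs()] / [scan_gene_ssrs()].
#' @return A one-row tibble: `n_loci`, `n_period_2` .. `n_period_6`,
#'   `dinucleotide_share` (percent), `modal_motif`, `modal_count`,
#'   `longest_motif`, `longest_repeats`, `longest_span`.
#' @export
summarize_ssrs <- function(loci) {
  periods <- 2:6
  if (nrow(loci) == 0) {
    out <- tibble(n_loci = 0L)
    for (p in periods) out[[paste0("n_period_", p)]] <- 0L
    return(out %>% mutate(dinucleotide_share = NA_real_,
                          modal_motif = NA_character_, modal_count = 0L,
                          longest_motif = NA_character_,
                          longest_repeats = NA_integer_,
                          longest_span = NA_integer_))
  }
  plen <- nchar(loci$motif)
  out <- tibble(n_loci = nrow(loci))
  for (p in periods) out[[paste0("n_period_", p)]] <- sum(plen == p)
  tab <- table(loci$motif)
  modal <- sort(names(tab)[tab == max(tab)])[1]
  span <- plen * loci$repeats
  best <- which(span == max(span))
  best <- best[order(loci$motif[best])][1]
  out %>% mutate(
    dinucleotide_share = 100 * sum(plen == 2) / nrow(loci),
    modal_motif = modal, modal_count = as.integer(max(tab)),
    longest_motif = loci$motif[best],
    longest_repeats = as.integer(loci$repeats[best]),
    longest_span = as.integer(span[best]))
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Load the bundled cis-regulatory element dictionary
#'
#' An editable YAML dictionary of element names and IUPAC consensus strings
#' in the style of plant promoter-element catalogs (TATA-box, CAAT-box,
#' ABRE, G-box, MBS, ...). Matching is consensus-based.
#'
#' @param file YAML file; default the packaged dictionary.
#' @return A tibble: `element_name`, `consensus`.
#' @export
cis_element_dictionary <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "cis_elements.yaml", package = "mybkit",
                        mustWork = TRUE)
  }
  d <- yaml::read_yaml(file)
  tibble(element_name = names(d$elements),
         consensus = unname(unlist(d$elements)))
}

#' Scan a sequence for cis-regulatory elements
#'
#' Finds all exact IUPAC-consensus matches of each dictionary element on both
#' strands. Minus-strand hits are reported at the forward-strand coordinate
#' of the match start.
#'
#' @param sequence DNA sequence (single string).
#' @param element_dictionary Tibble with `element_name` and `consensus`
#'   (IUPAC), default [cis_element_dictionary()].
#' @return A tibble sorted by position: `element_name`, `consensus`,
#'   `position` (1-based forward coordinate of the match start), `strand`,
#'   `match` (the matched forward-strand substring).
#' @export
scan_cis_elements <- function(sequence,
                              element_dictionary = cis_element_dictionary()) {
  check_dna(sequence, allow_n = TRUE, what = "promoter")
  bad <- element_dictionary$consensus[
    grepl(paste0("[^", paste(names(IUPAC_CODES), collapse = ""), "]"),
          element_dictionary$consensus)]
  if (length(bad) > 0) {
    stop("invalid IUPAC consensus in dictionary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  subj <- Biostrings::DNAString(sequence)
  out <- purrr::map_dfr(seq_len(nrow(element_dictionary)), function(i) {
    name <- element_dictionary$element_name[i]
    cons <- element_dictionary$consensus[i]
    fwd <- Biostrings::matchPattern(cons, subj, fixed = "subject")
    rev_pat <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    rev <- Biostrings::matchPattern(rev_pat, subj, fixed = "subject")
    dplyr::bind_rows(
      if (length(fwd) > 0) tibble(element_name = name, consensus = cons,
                                  position = Biostrings::start(fwd),
                                  strand = "+",
                                  match = as.character(fwd)),
      if (length(rev) > 0) tibble(element_name = name, consensus = cons,
                                  position = Biostrings::start(rev),
                                  strand = "-",
                                  match = as.character(rev)))
  })
  if (nrow(out) == 0) {
    return(tibble(element_name = character(), consensus = character(),
                  position = integer(), strand = character(),
                  match = character()))
  }
  out %>% arrange(.data$position, .data$element_name, .data$strand)
}
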