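# MYB repeat detection. The screen is profile + anchor-rule based: a bundled
# position-weight profile (built from a seed alignment shipped with the
# package) scores candidate windows, and tryptophan-anchor spacing rules
# (three Trp anchors spaced 20-21 aa in R2-type repeats; Phe/Trp then two Trp
# spaced 19 aa in R3-type repeats) propose the candidates.

#' Load the bundled MYB repeat profile
#'
#' Builds the repeat profile from the packaged seed alignment (a synthetic
#' alignment with the anchor architecture of plant MYB repeats; see the
#' methods vignette) and the profile configuration file: per-column residue
#' weights with a Laplace pseudocount, anchor rules, the calibrated score
#' threshold and the maximum inter-repeat linker.
#'
#' @param profile_file YAML profile configuration; default the packaged one.
#' @return A list of class `myb_profile` with elements `repeats` (per repeat
#'   type: weight matrix, anchor columns, allowed anchor residues, spacing
#'   rules), `score_threshold` and `max_linker`.
#' @export
myb_profile <- function(profile_file = NULL) {
  if (is.null(profile_file)) {
    if (!is.null(.mybkit_cache$profile)) return(.mybkit_cache$profile)
    profile_file <- system.file("extdata", "myb_profile.yaml",
                                package = "mybkit", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(profile_file)
  aln_file <- file.path(dirname(profile_file), cfg$seed_alignment)
  seqs <- Biostrings::readAAStringSet(aln_file)
  seqs <- setNames(as.character(seqs), names(seqs))
  reps <- lapply(names(cfg$repeats), function(type) {
    rc <- cfg$repeats[[type]]
    members <- seqs[startsWith(names(seqs), paste0(type, "_"))]
    stopifnot(length(members) >= 2, all(nchar(members) == rc$length))
    counts <- matrix(0L, nrow = 20, ncol = rc$length,
                     dimnames = list(AMINO_ACIDS, NULL))
    for (s in members) {
      ch <- split1(s)
      for (j in seq_along(ch)) counts[ch[j], j] <- counts[ch[j], j] + 1L
    }
    w <- sweep(counts + 0.05, 2, colSums(counts) + 1, "/")
    list(type = type,
         length = rc$length,
         weights = w,
         anchors = as.integer(rc$anchors),
         anchor_residues = lapply(rc$anchor_residues, split1),
         spacings = rc$spacings)
  })
  names(reps) <- names(cfg$repeats)
  prof <- structure(list(repeats = reps,
                         score_threshold = cfg$score_threshold,
                         max_linker = cfg$max_linker),
                    class = "myb_profile")
  if (is.null(.mybkit_cache$profile) &&
      basename(profile_file) == "myb_profile.yaml") {
    .mybkit_cache$profile <- prof
  }
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column log-odds score of a residue window against a weight matrix restricted
# to `cols`; X scores 0 (background)
profile_score <- function(residues, weights, cols) {
  s <- 0
  bg <- 1 / 20
  for (k in seq_along(cols)) {
    r <- residues[k]
    if (r == "X") next
    s <- s + log(weights[r, cols[k]] / bg)
  }
  s
}

# enumerate anchor-triple candidates for one repeat type; returns a tibble of
# candidate windows with anchors, start/end (1-based inclusive) and score
repeat_candidates <- function(res, rep_cfg) {
  n <- length(res)
  a1_allowed <- rep_cfg$anchor_residues[[1]]
  a2_allowed <- rep_cfg$anchor_residues[[2]]
  a3_allowed <- rep_cfg$anchor_residues[[3]]
  first_col <- rep_cfg$anchors[1]
  sp1 <- rep_cfg$spacings[[1]]; sp2 <- rep_cfg$spacings[[2]]
  out <- list()
  for (a1 in which(res %in% a1_allowed)) {
    for (s1 in sp1$min:sp1$max) {
      a2 <- a1 + s1
      if (a2 > n || !(res[a2] %in% a2_allowed)) next
      for (s2 in sp2$min:sp2$max) {
        a3 <- a2 + s2
        if (a3 > n || !(res[a3] %in% a3_allowed)) next
        cols <- seq_len(rep_cfg$length)
        drop <- c(
          if (s1 < sp1$max && !is.null(sp1$skip_column)) sp1$skip_column,
          if (s2 < sp2$max && !is.null(sp2$skip_column)) sp2$skip_column)
        if (length(drop) > 0) cols <- cols[-drop]
        start <- a1 - (first_col - 1)
        end <- start + length(cols) - 1
        if (start < 1 || end > n) next
        sc <- profile_score(res[start:end], rep_cfg$weights, cols)
        out[[length(out) + 1]] <- tibble(
          type = rep_cfg$type, start = start, end = end,
          anchor1 = a1, anchor2 = a2, anchor3 = a3, score = sc)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Detect MYB repeats in a protein sequence
#'
#' Proposes candidate repeat windows from the anchor rules (tryptophan /
#' phenylalanine anchors at the stereotypical spacings), scores each window
#' against the bundled profile, keeps windows scoring at or above the
#' threshold, and resolves overlaps greedily, best score first (ties broken
#' by smaller start).
#'
#' @param protein Amino-acid sequence (standard alphabet; `X` tolerated, never
#'   matches an anchor).
#' @param profile A [myb_profile()].
#' @return A tibble of non-overlapping repeats sorted by `start`: `type`
#'   (R2/R3-style anchor rule matched), `start`, `end` (1-based inclusive),
#'   `anchor1..3` (anchor residue positions) and `score`.
#' @export
detect_myb_repeats <- function(protein, profile = myb_profile()) {
  check_protein(protein)
  res <- split1(protein)
  cands <- dplyr::bind_rows(
    lapply(profile$repeats, repeat_candidates, res = res))
  if (nrow(cands) == 0) return(empty_repeat_table())
  cands <- cands %>%
    filter(.data$score >= profile$score_threshold) %>%
    arrange(desc(.data$score), .data$start)
  if (nrow(cands) == 0) return(empty_repeat_table())
  kept <- list()
  occupied <- rep(FALSE, length(res))
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    if (any(occupied[cand$start:cand$end])) next
    occupied[cand$start:cand$end] <- TRUE
    kept[[length(kept) + 1]] <- cand
  }
  dplyr::bind_rows(kept) %>% arrange(.data$start)
}

empty_repeat_table <- function() {
  tibble(type = character(), start = integer(), end = integer(),
         anchor1 = integer(), anchor2 = integer(), anchor3 = integer(),
         score = numeric())
}

#' Classify a protein into a MYB class from its detected repeats
#'
#' With `n` mutually adjacent repeats (each inter-repeat gap at most
#' `max_linker` residues) the class is `1R`, `R2R3`, `3R` or `4R` for
#' `n = 1..4`. Repeats present but violating adjacency (or more than four)
#' give `atypical`; zero repeats give `none` (not a MYB, distinct from
#' atypical).
#'
#' @param repeats Repeat table from [detect_myb_repeats()] for one protein.
#' @param protein_length Protein length (aa).
#' @param profile A [myb_profile()] supplying `max_linker`.
#' @return A one-row tibble: `n_repeats`, `myb_class`.
#' @export
classify_myb <- function(repeats, protein_length, profile = myb_profile()) {
  n <- nrow(repeats)
  if (n == 0) return(tibble(n_repeats = 0L, myb_class = "none"))
  reps <- repeats %>% arrange(.data$start)
  if (any(reps$end > protein_length) ||
      (n > 1 && any(reps$start[-1] <= reps$end[-n]))) {
    stop("repeats overlap or exceed the protein: contract violation",
         call. = FALSE)
  }
  gaps <- if (n > 1) reps$start[-1] - reps$end[-n] - 1 else integer(0)
  adjacent <- all(gaps <= profile$max_linker)
  cls <- if (!adjacent || n > 4) "atypical"
         else c("1R", "R2R3", "3R", "4R")[n]
  tibble(n_repeats = as.integer(n), myb_class = cls)
}

#' Identify and classify MYB proteins in a proteome
#'
#' Runs [detect_myb_repeats()] and [classify_myb()] over a set of proteins.
#'
#' @param proteins Named character vector of protein sequences, or a data
#'   frame with columns `protein_id` and `protein`.
#' @param profile A [myb_profile()].
#' @return A list with `classification` (tibble: `protein_id`, `n_repeats`,
#'   `myb_class`) and `repeats` (tibble of all detected repeats with
#'   `protein_id`).
#' @export
identify_myb <- function(proteins, profile = myb_profile()) {
  if (is.character(proteins)) {
    proteins <- tibble(protein_id = names(proteins), protein = unname(proteins))
  }
  stopifnot(all(c("protein_id", "protein") %in% names(proteins)))
  reps <- purrr::map(seq_len(nrow(proteins)), function(i) {
    r <- detect_myb_repeats(proteins$protein[i], profile)
    if (nrow(r) > 0) dplyr::bind_cols(
      tibble(protein_id = proteins$protein_id[i]), r)
    else NULL
  })
  repeats <- dplyr::bind_rows(reps)
  classification <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    id <- proteins$protein_id[i]
    r <- if (nrow(repeats) > 0) repeats %>% filter(.data$protein_id == id)
         else empty_repeat_table()
    dplyr::bind_cols(tibble(protein_id = id),
                     classify_myb(r, nchar(proteins$protein[i]), profile))
  })
  list(classification = classification, repeats = repeats)
}

#' Column conservation profile of aligned repeat blocks
#'
#' For equal-length amino-acid blocks, computes the modal residue and its
#' frequency per column (gap characters `-` are excluded from modal counts
#' but remain in the denominator, i.e. frequency is over all sequences), and
#' counts columns whose modal frequency reaches the conservation threshold
#' (inclusive).
#'
#' @param repeat_blocks Character vector (>= 2) of equal-length amino-acid
#'   strings, `-` allowed.
#' @param threshold Conservation threshold, default 0.80.
#' @return An object of class `conservation_profile`: list with
#'   `n_sequences`, `column_stats` (tibble: `position`, `modal_residue`,
#'   `modal_freq`), `threshold`, `n_conserved`.
#' @export
build_conservation_profile <- function(repeat_blocks, threshold = 0.80) {
  stopifnot(length(repeat_blocks) >= 2, threshold >= 0, threshold <= 1)
  lens <- nchar(repeat_blocks)
  if (length(unique(lens)) != 1) {
    stop("repeat blocks must all have the same length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(repeat_blocks, ""))
  n <- nrow(mat)
  stats <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0) {
      return(tibble(position = j, modal_residue = NA_character_,
                    modal_freq = 0))
    }
    tab <- sort(table(col), decreasing = TRUE)
    # deterministic tie-break: alphabetically smallest among the modes
    modes <- names(tab)[tab == tab[1]]
    tibble(position = j, modal_residue = sort(modes)[1],
           modal_freq = as.numeric(tab[1]) / n)
  })
  structure(list(n_sequences = n, column_stats = stats,
                 threshold = threshold,
                 n_conserved = sum(stats$modal_freq >= threshold)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile:", x$n_sequences, "sequences,",
      nrow(x$column_stats), "columns\n")
  cat(x$n_conserved, "column(s) conserved at threshold", x$threshold, "\n")
  invisible(x)
}

#' Anchor spacing histogram
#'
#' Tallies the distances between successive matched anchor residues, per
#' anchor pair, across a set of detected repeats. Distances are residue
#' offsets (`anchor2 - anchor1`).
#'
#' @param repeats Repeat table with `anchor1`, `anchor2`, `anchor3` columns
#'   (as from [detect_myb_repeats()]); repeats with fewer than two anchors
#'   contribute nothing.
#' @return A tibble `anchor_pair` (`"1-2"`, `"2-3"`), `spacing`, `n`.
#' @export
anchor_spacing_stats <- function(repeats) {
  if (nrow(repeats) == 0) {
    return(tibble(anchor_pair = character(), spacing = integer(),
                  n = integer()))
  }
  long <- dplyr::bind_rows(
    tibble(anchor_pair = "1-2",
           spacing = repeats$anchor2 - repeats$anchor1),
    tibble(anchor_pair = "2-3",
           spacing = repeats$anchor3 - repeats$anchor2))
  long %>%
    filter(!is.na(.data$spacing)) %>%
    dplyr::count(.data$anchor_pair, .data$spacing, name = "n") %>%
    arrange(.data$anchor_pair, .data$spacing)
}
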