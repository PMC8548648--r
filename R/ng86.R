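# Nei-Gojobori (1986) counting: fractional synonymous-site counting per codon,
# pathway-averaged difference counting, Jukes-Cantor multiple-hit correction.
#
# Conventions (documented in the methods vignette):
#   * changes to stop codons are excluded consistently from both site and
#     difference counting: the synonymous fraction per position is taken over
#     the non-stop alternatives (each codon still contributes 3 sites);
#   * mutational pathways that pass through a stop codon are excluded from
#     difference averaging; remaining pathways get equal weight;
#   * codon pairs whose every pathway is blocked by stops are skipped and
#     counted in `n_skipped`.

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# lazily built lookup tables: per-codon synonymous site counts and 64x64
# pathway-averaged (Sd, Nd) matrices
ng86_tables <- function() {
  if (!is.null(.mybkit_cache$ng86)) return(.mybkit_cache$ng86)
  code <- genetic_code()
  codons <- names(code)
  nc <- length(codons)

  # fraction of synonymous changes per position among non-stop alternatives
  # (changes to stop codons are excluded from site counting, mirroring their
  # exclusion from pathway counting); each codon still contributes 3 sites
  syn_sites <- vapply(codons, function(cd) {
    if (code[[cd]] == "*") return(NA_real_)
    s <- 0
    for (pos in 1:3) {
      n_syn <- 0; n_nonstop <- 0
      for (alt in setdiff(DNA_BASES, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- alt
        if (code[[mut]] == "*") next
        n_nonstop <- n_nonstop + 1
        if (code[[mut]] == code[[cd]]) n_syn <- n_syn + 1
      }
      if (n_nonstop > 0) s <- s + n_syn / n_nonstop
    }
    s
  }, numeric(1))

  perms <- list(
    `1` = matrix(1, 1, 1),
    `2` = rbind(c(1, 2), c(2, 1)),
    `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  )

  Sd <- matrix(NA_real_, nc, nc, dimnames = list(codons, codons))
  Nd <- matrix(NA_real_, nc, nc, dimnames = list(codons, codons))
  for (i in seq_len(nc)) {
    ci <- codons[i]
    if (code[[ci]] == "*") next
    for (j in seq_len(nc)) {
      cj <- codons[j]
      if (code[[cj]] == "*") next
      diffpos <- which(split1(ci) != split1(cj))
      d <- length(diffpos)
      if (d == 0) {
        Sd[i, j] <- 0; Nd[i, j] <- 0
        next
      }
      ords <- perms[[as.character(d)]]
      sd_tot <- 0; nd_tot <- 0; n_ok <- 0
      for (r in seq_len(nrow(ords))) {
        cur <- ci
        sd <- 0; nd <- 0; ok <- TRUE
        for (p in diffpos[ords[r, seq_len(d)]]) {
          nxt <- cur
          substr(nxt, p, p) <- substr(cj, p, p)
          if (code[[nxt]] == "*") { ok <- FALSE; break }
          if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1 }
      }
      if (n_ok > 0) {
        Sd[i, j] <- sd_tot / n_ok
        Nd[i, j] <- nd_tot / n_ok
      }
    }
  }
  .mybkit_cache$ng86 <- list(code = code, syn_sites = syn_sites, Sd = Sd, Nd = Nd)
  .mybkit_cache$ng86
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks from an aligned codon pair
#'
#' Implements the Nei-Gojobori (1986) counting method: synonymous sites are
#' counted fractionally per codon under the standard genetic code, differences
#' per codon pair are averaged over all minimal mutational pathways with equal
#' weights (pathways through stop codons excluded), and the proportions are
#' Jukes-Cantor corrected, \eqn{K = -\frac{3}{4}\log(1 - \frac{4}{3}p)}.
#'
#' @param codon_alignment A data frame with columns `codon_a` and `codon_b`
#'   (three-letter codons; `"---"` marks a codon gap), as produced by
#'   [codon_align()]. Gap columns are excluded from counting.
#' @return A one-row tibble with `Ka`, `Ks`, `omega` (`NA` when `Ks` is 0 or
#'   saturated), the site and difference counts `S`, `N`, `Sd`, `Nd`, the
#'   proportions `pS`, `pN`, the number of compared codons `n_codons`, and
#'   `n_skipped` (codon pairs whose every pathway hits a stop).
#' @export
#' @examples
#' aln <- codon_align(list(aligned_a = "MK", aligned_b = "MK"),
#'                    "ATGAAA", "ATGAAG")
#' ng86_ka_ks(aln)
ng86_ka_ks <- function(codon_alignment) {
  stopifnot(all(c("codon_a", "codon_b") %in% names(codon_alignment)))
  tab <- ng86_tables()
  a <- codon_alignment$codon_a
  b <- codon_alignment$codon_b
  keep <- !grepl("-", a, fixed = TRUE) & !grepl("-", b, fixed = TRUE)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("no gap-free codon columns to compare", call. = FALSE)
  bad <- !(a %in% names(tab$code)) | !(b %in% names(tab$code)) |
    tab$code[a] == "*" | tab$code[b] == "*"
  if (any(bad)) stop("codon alignment contains stop or invalid codons",
                     call. = FALSE)
  S <- (sum(tab$syn_sites[a]) + sum(tab$syn_sites[b])) / 2
  N <- 3 * length(a) - S
  sd_i <- tab$Sd[cbind(a, b)]
  nd_i <- tab$Nd[cbind(a, b)]
  skipped <- is.na(sd_i)
  if (any(skipped)) {
    warning(sum(skipped), " codon pair(s) skipped: all pathways hit stop codons")
  }
  Sd <- sum(sd_i[!skipped]); Nd <- sum(nd_i[!skipped])
  pS <- Sd / S; pN <- Nd / N
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  omega <- if (is.na(Ka) || is.na(Ks) || Ks <= 0) NA_real_ else Ka / Ks
  tibble(
    Ka = Ka, Ks = Ks, omega = omega,
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    n_codons = length(a), n_skipped = sum(skipped)
  )
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Maps an aligned protein pair back to codons: each aligned residue becomes
#' its source codon and each gap column becomes a `"---"` codon gap. The
#' aligned residues must re-translate to the codons they are mapped to, which
#' guards against mismatched protein/CDS inputs.
#'
#' @param protein_alignment A list or one-row data frame with elements
#'   `aligned_a` and `aligned_b` (gapped aligned strings) and optionally
#'   `start_a`, `start_b` (1-based residue offsets of the aligned region in
#'   the full proteins; default 1), as produced by [align_protein_pair()].
#' @param cds_a,cds_b Coding sequences of the two (unaligned) proteins.
#' @return A tibble with columns `codon_a`, `codon_b`, one row per alignment
#'   column.
#' @export
codon_align <- function(protein_alignment, cds_a, cds_b) {
  pa <- as.list(protein_alignment)
  aln_a <- split1(as.character(pa$aligned_a))
  aln_b <- split1(as.character(pa$aligned_b))
  if (length(aln_a) != length(aln_b)) {
    stop("aligned strings differ in length", call. = FALSE)
  }
  start_a <- if (is.null(pa$start_a)) 1L else as.integer(pa$start_a)
  start_b <- if (is.null(pa$start_b)) 1L else as.integer(pa$start_b)
  prot_a <- translate_cds(cds_a)
  prot_b <- translate_cds(cds_b)
  codons_of <- function(cds) {
    substring(cds, seq(1, nchar(cds) - 2, by = 3), seq(3, nchar(cds), by = 3))
  }
  cod_a <- codons_of(cds_a)
  cod_b <- codons_of(cds_b)
  ia <- start_a - 1L; ib <- start_b - 1L
  out_a <- character(length(aln_a)); out_b <- character(length(aln_b))
  for (k in seq_along(aln_a)) {
    if (aln_a[k] == "-") {
      out_a[k] <- "---"
    } else {
      ia <- ia + 1L
      if (ia > nchar(prot_a) || substr(prot_a, ia, ia) != aln_a[k]) {
        stop("protein alignment does not match translation of cds_a",
             call. = FALSE)
      }
      out_a[k] <- cod_a[ia]
    }
    if (aln_b[k] == "-") {
      out_b[k] <- "---"
    } else {
      ib <- ib + 1L
      if (ib > nchar(prot_b) || substr(prot_b, ib, ib) != aln_b[k]) {
        stop("protein alignment does not match translation of cds_b",
             call. = FALSE)
      }
      out_b[k] <- cod_b[ib]
    }
  }
  tibble(codon_a = out_a, codon_b = out_b)
}
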