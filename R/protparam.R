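# ProtParam-style physicochemical descriptors. Constant tables follow the
# conventions of the Expasy ProtParam service: average (not monoisotopic)
# residue masses, the Bjellqvist pKa set with position-specific terminal
# values, Kyte-Doolittle hydropathy, and the Guruprasad dipeptide instability
# weights (DIWV, shipped as a data file).

# average masses of the free amino acids (Da); residue mass = value - water
AA_FREE_MASS <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885)
WATER_MASS <- 18.0153

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Bjellqvist pKa set (as used by ProtParam)
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                          V = 7.44, E = 7.7)
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

diwv_table <- function() {
  if (!is.null(.mybkit_cache$diwv)) return(.mybkit_cache$diwv)
  path <- system.file("extdata", "diwv.tsv", package = "mybkit",
                      mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- matrix(NA_real_, 20, 20, dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
  m[cbind(d$first, d$second)] <- d$weight
  .mybkit_cache$diwv <- m
  m
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass (ProtParam convention).
#'
#' @param protein Amino-acid sequence (standard 20-letter alphabet).
#' @return Molecular weight in Da.
#' @export
#' @examples
#' molecular_weight("G")   # 75.07
#' molecular_weight("GG")  # 132.12
molecular_weight <- function(protein) {
  check_protein(protein, allow_x = FALSE)
  res <- split1(protein)
  sum(AA_FREE_MASS[res] - WATER_MASS) + WATER_MASS
}

protein_net_charge <- function(counts, first, last, pH) {
  pos_pk <- c(Nterm = unname(
    PKA_NTERM_BY_RESIDUE[first] %|NA|% PKA_POSITIVE[["Nterm"]]),
    PKA_POSITIVE[c("K", "R", "H")])
  neg_pk <- c(Cterm = unname(
    PKA_CTERM_BY_RESIDUE[last] %|NA|% PKA_NEGATIVE[["Cterm"]]),
    PKA_NEGATIVE[c("D", "E", "C", "Y")])
  n_pos <- c(Nterm = 1, K = counts[["K"]], R = counts[["R"]],
             H = counts[["H"]])
  n_neg <- c(Cterm = 1, D = counts[["D"]], E = counts[["E"]],
             C = counts[["C"]], Y = counts[["Y"]])
  sum(n_pos / (1 + 10^(pH - pos_pk))) - sum(n_neg / (1 + 10^(neg_pk - pH)))
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge over the termini and
#' the ionizable side chains (D, E, C, Y, H, K, R; Bjellqvist pKa set) is
#' zero, found by bisection on `[0, 14]` to `|charge| < 1e-4`.
#'
#' @param protein Amino-acid sequence.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein) {
  check_protein(protein, allow_x = FALSE)
  res <- split1(protein)
  counts <- table(factor(res, levels = AMINO_ACIDS))
  first <- res[1]; last <- res[length(res)]
  lo <- 0; hi <- 14
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    q <- protein_net_charge(counts, first, last, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues.
#'
#' @param protein Amino-acid sequence.
#' @return GRAVY score (dimensionless).
#' @export
gravy <- function(protein) {
  check_protein(protein, allow_x = FALSE)
  mean(KYTE_DOOLITTLE[split1(protein)])
}

#' Aliphatic index
#'
#' `AI = X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` with `X` the mole percent
#' of each residue.
#'
#' @param protein Amino-acid sequence.
#' @return Aliphatic index (dimensionless).
#' @export
aliphatic_index <- function(protein) {
  check_protein(protein, allow_x = FALSE)
  res <- split1(protein)
  x <- 100 * table(factor(res, levels = AMINO_ACIDS)) / length(res)
  unname(x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]]))
}

#' Instability index
#'
#' `II = (10 / L) * sum of DIWV weights` over the L-1 overlapping dipeptides
#' (Guruprasad weights). Values above 40 predict an unstable protein.
#'
#' @param protein Amino-acid sequence, length >= 2.
#' @return Instability index (dimensionless).
#' @export
instability_index <- function(protein) {
  check_protein(protein, allow_x = FALSE)
  res <- split1(protein)
  if (length(res) < 2) {
    stop("instability index requires length >= 2", call. = FALSE)
  }
  w <- diwv_table()
  L <- length(res)
  10 / L * sum(w[cbind(res[-L], res[-1])])
}

#' ProtParam-style descriptor table for a set of proteins
#'
#' @param proteins Named character vector of protein sequences, or a data
#'   frame with `protein_id` and `protein`.
#' @return A tibble: `protein_id`, `length`, `mw`, `pI`, `gravy`,
#'   `aliphatic_index`, `instability_index`, `stability_call` (`"unstable"`
#'   iff instability index > 40).
#' @export
protein_properties <- function(proteins) {
  if (is.character(proteins)) {
    proteins <- tibble(protein_id = names(proteins) %||%
                         paste0("p", seq_along(proteins)),
                       protein = unname(proteins))
  }
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    p <- proteins$protein[i]
    ii <- instability_index(p)
    tibble(protein_id = proteins$protein_id[i],
           length = nchar(p),
           mw = molecular_weight(p),
           pI = isoelectric_point(p),
           gravy = gravy(p),
           aliphatic_index = aliphatic_index(p),
           instability_index = ii,
           stability_call = ifelse(ii > 40, "unstable", "stable"))
  })
}
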