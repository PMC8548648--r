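#' Derive a child random seed from a root seed and a stream label
#'
#' All stochastic components of the simulator draw from their own stream,
#' derived deterministically from one root seed and a fixed label, so that a
#' component can be regenerated in isolation without disturbing the others.
#'
#' @param seed Integer root seed.
#' @param label Character stream label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(max(1, h))
}

# evaluate `expr` under a local RNG state seeded from (seed, label)
with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, label))
  expr
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA_BASES <- c("A", "C", "G", "T")

check_protein <- function(x, allow_x = TRUE, what = "protein") {
  stopifnot(is.character(x), length(x) == 1)
  if (nchar(x) == 0) stop(what, " sequence must be non-empty", call. = FALSE)
  ok <- AMINO_ACIDS
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), ok)
  if (length(bad) > 0) {
    stop("invalid residue(s) in ", what, " sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

check_dna <- function(x, allow_n = TRUE, what = "DNA") {
  stopifnot(is.character(x), length(x) == 1)
  ok <- DNA_BASES
  if (allow_n) ok <- c(ok, "N")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), ok)
  if (length(bad) > 0) {
    stop("invalid base(s) in ", what, " sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate coding sequences to protein
#'
#' Standard genetic code; a single trailing stop codon is dropped. Internal
#' stop codons are an error.
#'
#' @param cds Character vector of coding sequences (length divisible by 3).
#' @return Character vector of amino-acid sequences.
#' @export
translate_cds <- function(cds) {
  vapply(cds, function(s) {
    if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3", call. = FALSE)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), no.init.codon = TRUE))
    if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
    if (grepl("\\*", aa)) stop("internal stop codon in CDS", call. = FALSE)
    aa
  }, character(1), USE.NAMES = !is.null(names(cds)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# random protein stretch; tryptophan can be excluded so that planted repeat
# anchors stay unambiguous in simulated flanks
random_protein <- function(n, exclude = character(0)) {
  paste(sample(setdiff(AMINO_ACIDS, exclude), n, replace = TRUE), collapse = "")
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# coerce a genes x samples count input (matrix or tibble with gene_id column)
# to an integer-like matrix with gene rownames
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
  } else if (is.data.frame(counts)) {
    stopifnot("gene_id" %in% names(counts))
    m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
    rownames(m) <- counts$gene_id
  } else {
    stop("counts must be a matrix or a data frame with a gene_id column",
         call. = FALSE)
  }
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  m
}
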