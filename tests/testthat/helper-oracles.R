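# Independent brute-force oracles used to validate the production
# implementations on small inputs. These deliberately re-derive each quantity
# from first principles (direct enumeration) rather than reusing the package
# code paths.

# --- NG86 oracle: exhaustive site and pathway enumeration -------------------

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)

oracle_mutations <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      out <- c(out, mut)
    }
  }
  out
}

# synonymous sites of one codon: per position, fraction of synonymous changes
# among non-stop alternatives
oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    alts <- character(0)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (oracle_code[[mut]] != "*") alts <- c(alts, mut)
    }
    if (length(alts) > 0) {
      s <- s + mean(oracle_code[alts] == oracle_code[[codon]])
    }
  }
  s
}

# all orderings of the differing positions, as a list of position vectors
oracle_orderings <- function(pos) {
  if (length(pos) <= 1) return(list(pos))
  out <- list()
  for (i in seq_along(pos)) {
    for (rest in oracle_orderings(pos[-i])) {
      out[[length(out) + 1]] <- c(pos[i], rest)
    }
  }
  out
}

# pathway-averaged (Sd, Nd) for one codon pair; NA if every pathway is
# blocked by a stop codon
oracle_pair_diffs <- function(c1, c2) {
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffpos) == 0) return(c(Sd = 0, Nd = 0))
  acc <- c(0, 0)
  n_ok <- 0
  for (ord in oracle_orderings(diffpos)) {
    cur <- c1
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_code[[nxt]] == "*") { ok <- FALSE; break }
      if (oracle_code[[nxt]] == oracle_code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(sd, nd); n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(c(Sd = NA_real_, Nd = NA_real_))
  acc / n_ok
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
        sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(codons_a)) {
    d <- oracle_pair_diffs(codons_a[k], codons_b[k])
    if (!anyNA(d)) { Sd <- Sd + unname(d[1]); Nd <- Nd + unname(d[2]) }
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
       Ka = jc(Nd / N), Ks = jc(Sd / S))
}

random_sense_codons <- function(n) {
  sense <- names(oracle_code)[oracle_code != "*"]
  sample(sense, n, replace = TRUE)
}

codons_of <- function(s) {
  substring(s, seq(1, nchar(s) - 2, by = 3), seq(3, nchar(s), by = 3))
}

# --- exhaustive best-chain oracle for synteny -------------------------------

# best chain score over all anchor subsets and both orientations
oracle_best_chain_score <- function(anchors, config) {
  n <- nrow(anchors)
  best <- -Inf
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    sub <- anchors[idx, ]
    sub <- sub[order(sub$rank_a), ]
    for (orient in c(1, -1)) {
      da <- diff(sub$rank_a)
      db <- orient * diff(sub$rank_b)
      if (length(da) > 0 &&
          (any(da < 1) || any(db < 1) ||
           any(da > config$max_rank_gap) || any(db > config$max_rank_gap))) next
      score <- nrow(sub) -
        config$gap_penalty * sum((da - 1) + (db - 1))
      if (score > best) best <- score
      if (nrow(sub) == 1) break  # orientation irrelevant for singletons
    }
  }
  best
}

# --- quadratic brute-force SSR scanner --------------------------------------

oracle_find_ssrs <- function(seq, min_motif = 2, max_motif = 6,
                             min_repeats = 6) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  minimal <- function(m) {
    p <- nchar(m)
    for (d in seq_len(p - 1)) {
      if (p %% d == 0 && m == strrep(substr(m, 1, d), p / d)) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (p in min_motif:max_motif) {
    for (i in seq_len(max(0, L - p * min_repeats + 1))) {
      motif <- substr(seq, i, i + p - 1)
      if (grepl("N", motif)) next
      if (!minimal(motif)) next
      # count full copies at i
      r <- 1
      while (i + (r + 1) * p - 1 <= L &&
             substr(seq, i + r * p, i + (r + 1) * p - 1) == motif) r <- r + 1
      if (r < min_repeats) next
      # leftmost position of its maximal run: no partial extension left
      if (i > 1 && ch[i - 1] == ch[i - 1 + p]) next
      out[[length(out) + 1]] <- data.frame(
        motif = motif, repeats = r, start = i, end = i + p * r - 1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(data.frame(motif = character(),
                                        repeats = integer(),
                                        start = integer(),
                                        end = integer()))))
}

# --- direct-formula Benjamini-Hochberg --------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- misc helpers -----------------------------------------------------------

random_protein_str <- function(n, alphabet = strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
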