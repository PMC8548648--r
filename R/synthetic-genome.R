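#' Simulation configuration for the synthetic gene-family genome
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' small plant gene-family study: compact chromosomes, CDS-sized genes, MYB
#' repeats of the canonical classes planted in a subset of proteins, and a
#' three-fruit-stage (EG/MG/Br) expression design with three biological
#' replicates.
#'
#' @param seed Integer root seed; every stochastic component derives its own
#'   stream from it (see [child_seed()]), so a fixed seed gives byte-identical
#'   outputs.
#' @param n_chromosomes,genes_per_chromosome Genome layout.
#' @param gene_length_range CDS length interval in bp (rounded to codons).
#' @param intergenic_range Intergenic spacer length interval in bp.
#' @param chromosome_length Optional fixed chromosome capacity in bp; the
#'   generator errors, naming the chromosome, if its genes do not fit.
#' @param myb_classes Character vector of MYB classes (`"1R"`, `"R2R3"`,
#'   `"3R"`, `"4R"`) planted into the first proteins, one gene per entry,
#'   distributed round-robin over chromosomes.
#' @param duplication_events List of `list(mode, omega, target_ks)` with
#'   `mode` in `tandem`/`segmental`.
#' @param rearrangements List of `list(type, span)` with `type` in
#'   `inversion`/`translocation`, applied when deriving the partner gene
#'   order for synteny tests.
#' @param ssr_plantings List of `list(motif, repeats, region)` with `region`
#'   in `genic`/`upstream`.
#' @param de_plantings List with `fraction_de`, `log2fc_magnitude`,
#'   `dispersion`.
#' @param n_stages,n_replicates Expression design (defaults 3 x 3).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              genes_per_chromosome = 10L,
                              gene_length_range = c(300L, 900L),
                              intergenic_range = c(2000L, 8000L),
                              chromosome_length = NULL,
                              myb_classes = c("R2R3", "R2R3", "1R", "3R"),
                              duplication_events = list(),
                              rearrangements = list(),
                              ssr_plantings = list(),
                              de_plantings = list(fraction_de = 0.1,
                                                  log2fc_magnitude = 2,
                                                  dispersion = 0.1),
                              n_stages = 3L,
                              n_replicates = 3L) {
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 1,
            length(gene_length_range) == 2,
            gene_length_range[1] >= 30,
            gene_length_range[1] <= gene_length_range[2],
            length(intergenic_range) == 2,
            intergenic_range[1] >= 1,
            intergenic_range[1] <= intergenic_range[2],
            n_stages >= 1, n_replicates >= 1)
  stopifnot(all(myb_classes %in% c("1R", "R2R3", "3R", "4R")))
  if (length(myb_classes) > n_chromosomes * genes_per_chromosome) {
    stop("more MYB plantings than genes", call. = FALSE)
  }
  for (ev in duplication_events) {
    stopifnot(ev$mode %in% c("tandem", "segmental"),
              is.numeric(ev$omega), ev$omega >= 0,
              is.numeric(ev$target_ks), ev$target_ks >= 0)
  }
  for (rr in rearrangements) {
    stopifnot(rr$type %in% c("inversion", "translocation"),
              is.numeric(rr$span), rr$span >= 2)
  }
  for (sp in ssr_plantings) {
    stopifnot(is.character(sp$motif),
              nchar(sp$motif) >= 2, nchar(sp$motif) <= 6,
              !grepl("[^ACGT]", sp$motif),
              is.numeric(sp$repeats), sp$repeats >= 1,
              sp$region %in% c("genic", "upstream"))
  }
  stopifnot(is.numeric(de_plantings$fraction_de),
            de_plantings$fraction_de >= 0, de_plantings$fraction_de <= 1,
            de_plantings$dispersion >= 0)
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_range = as.integer(intergenic_range),
                 chromosome_length = chromosome_length,
                 myb_classes = myb_classes,
                 duplication_events = duplication_events,
                 rearrangements = rearrangements,
                 ssr_plantings = ssr_plantings,
                 de_plantings = de_plantings,
                 n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_config")
}

# sample one repeat instance from the bundled profile; returns residues,
# relative anchor positions and the repeat type
sample_repeat <- function(type, profile) {
  rc <- profile$repeats[[type]]
  cols <- seq_len(rc$length)
  anchors <- rc$anchors
  for (g in seq_along(rc$spacings)) {
    sp <- rc$spacings[[g]]
    s <- sample(sp$min:sp$max, 1)
    if (s < sp$max && !is.null(sp$skip_column)) {
      drop <- sp$skip_column
      cols <- setdiff(cols, drop)
    }
  }
  res <- vapply(cols, function(j) {
    sample(AMINO_ACIDS, 1, prob = rc$weights[, j])
  }, character(1))
  # force the anchors (profile columns are anchor-dominated already)
  anchor_pos <- match(anchors, cols)
  for (k in seq_along(anchor_pos)) {
    res[anchor_pos[k]] <- rc$anchor_residues[[k]][1]
  }
  list(seq = paste(res, collapse = ""), anchors = anchor_pos, type = type)
}

# repeat composition per MYB class; R2-style and R3-style repeats are the two
# bundled profiles, so higher classes reuse them (a documented simplification)
class_repeat_layout <- function(myb_class) {
  switch(myb_class,
         "1R" = "R3",
         "R2R3" = c("R2", "R3"),
         "3R" = c("R2", "R2", "R3"),
         "4R" = c("R2", "R2", "R2", "R3"),
         stop("unknown MYB class: ", myb_class, call. = FALSE))
}

#' Synthesize a protein with planted MYB repeats
#'
#' Emits a protein of the requested MYB class: repeats of ~52-53 aa sampled
#' from the bundled profile with their tryptophan/phenylalanine anchors forced
#' (R2-type: three Trp anchors spaced 20-21 aa; R3-type: Phe anchor then two
#' Trp spaced 19 aa), joined by short linkers and flanked by random sequence.
#' Tryptophan is excluded from flanks and linkers so the planted anchors stay
#' unambiguous.
#'
#' @param myb_class One of `"1R"`, `"R2R3"`, `"3R"`, `"4R"`.
#' @param seed Integer seed.
#' @param profile A [myb_profile()].
#' @return A list with `protein` (sequence, starting with M) and `repeats`
#'   (tibble: `type`, `start`, `end`, `anchor1..3`, 1-based inclusive).
#' @export
synthesize_myb_protein <- function(myb_class, seed, profile = myb_profile()) {
  layout <- class_repeat_layout(myb_class)
  with_stream(seed, paste0("mybprot_", myb_class), {
    nterm <- paste0("M", random_protein(sample(5:30, 1), exclude = "W"))
    parts <- nterm
    truth <- list()
    pos <- nchar(nterm)
    for (i in seq_along(layout)) {
      rep_i <- sample_repeat(layout[i], profile)
      start <- pos + 1
      end <- pos + nchar(rep_i$seq)
      truth[[i]] <- tibble(type = rep_i$type, start = start, end = end,
                           anchor1 = start + rep_i$anchors[1] - 1,
                           anchor2 = start + rep_i$anchors[2] - 1,
                           anchor3 = start + rep_i$anchors[3] - 1)
      parts <- c(parts, rep_i$seq)
      pos <- end
      if (i < length(layout)) {
        linker <- random_protein(sample(3:8, 1), exclude = "W")
        parts <- c(parts, linker)
        pos <- pos + nchar(linker)
      }
    }
    cterm <- random_protein(sample(10:40, 1), exclude = "W")
    list(protein = paste(c(parts, cterm), collapse = ""),
         repeats = dplyr::bind_rows(truth))
  })
}

# uniform random reverse translation of a protein (synonymous codons equally
# likely); no trailing stop is added here
reverse_translate <- function(protein) {
  code <- genetic_code()
  by_aa <- split(names(code), code)
  paste(vapply(split1(protein), function(aa) {
    sample(by_aa[[aa]], 1)
  }, character(1)), collapse = "")
}

#' Evolve a duplicate coding-sequence pair to a target synonymous divergence
#'
#' Proposal-acceptance codon evolution: single-nucleotide changes are proposed
#' uniformly; proposals creating stop codons are rejected; synonymous and
#' nonsynonymous proposals are accepted with probabilities chosen so that the
#' realized nonsynonymous/synonymous rate ratio equals `omega`
#' (`min(1, omega)` for nonsynonymous, `min(1, 1/omega)` for synonymous).
#' Evolution continues until the realized synonymous divergence -- accepted
#' synonymous substitutions per synonymous site (Jukes-Cantor scale) --
#' reaches `target_ks`.
#'
#' @param cds Coding sequence, length divisible by 3, no internal stops (a
#'   trailing stop codon is not allowed either; evolve the stop-free CDS).
#' @param omega Target nonsynonymous/synonymous rate ratio, >= 0.
#' @param target_ks Target synonymous substitutions per synonymous site;
#'   targets at or beyond the generator's saturation bound (1.0, i.e.
#'   0.75 x 4/3) are refused.
#' @param seed Integer seed.
#' @return A list with `cds_a` (the input), `cds_b` (the evolved copy) and
#'   `truth`, a one-row tibble recording `omega`, `target_ks`, the realized
#'   substitution counts and realized synonymous divergence.
#' @export
evolve_duplicate_pair <- function(cds, omega, target_ks, seed) {
  check_dna(cds, allow_n = FALSE, what = "CDS")
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3", call. = FALSE)
  stopifnot(omega >= 0, target_ks >= 0)
  if (target_ks >= 1) {
    stop("target_ks = ", target_ks, " is beyond the saturation bound (1.0): ",
         "synonymous divergence this high is not reliably realizable",
         call. = FALSE)
  }
  tab <- ng86_tables()
  codons_of <- function(s) substring(s, seq(1, nchar(s) - 2, 3),
                                     seq(3, nchar(s), 3))
  cod <- codons_of(cds)
  if (any(tab$code[cod] == "*")) {
    stop("CDS contains stop codon(s)", call. = FALSE)
  }
  p_nonsyn <- min(1, omega)
  p_syn <- if (omega > 1) 1 / omega else 1
  S_anc <- sum(tab$syn_sites[cod])
  b <- split1(cds)
  L <- length(b)
  m_syn <- 0; m_nonsyn <- 0
  S_cur <- S_anc
  # realized synonymous divergence is tracked as the observed Jukes-Cantor
  # corrected synonymous distance between the two current sequences
  sd_codon <- rep(0, length(cod))  # per-codon pathway-averaged Sd vs ancestor
  divergence <- 0
  if (target_ks > 0) {
    with_stream(seed, "evolve", {
      max_iter <- 1e7
      it <- 0
      while (divergence < target_ks) {
        it <- it + 1
        if (it > max_iter) stop("evolution did not converge", call. = FALSE)
        pos <- sample.int(L, 1)
        alt <- sample(setdiff(DNA_BASES, b[pos]), 1)
        ci <- (pos - 1) %/% 3
        old_codon <- paste(b[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
        new_codon <- old_codon
        substr(new_codon, pos - ci * 3, pos - ci * 3) <- alt
        if (tab$code[[new_codon]] == "*") next
        syn <- tab$code[[new_codon]] == tab$code[[old_codon]]
        p <- if (syn) p_syn else p_nonsyn
        if (p < 1 && runif(1) >= p) next
        b[pos] <- alt
        S_cur <- S_cur - tab$syn_sites[[old_codon]] + tab$syn_sites[[new_codon]]
        if (syn) m_syn <- m_syn + 1 else m_nonsyn <- m_nonsyn + 1
        sd_new <- tab$Sd[cod[ci + 1], new_codon]
        sd_codon[ci + 1] <- if (is.na(sd_new)) 0 else sd_new
        pS <- sum(sd_codon) / ((S_anc + S_cur) / 2)
        divergence <- if (pS >= 0.75) Inf else -0.75 * log(1 - 4 * pS / 3)
      }
    })
  }
  list(cds_a = cds,
       cds_b = paste(b, collapse = ""),
       truth = tibble(omega = omega, target_ks = target_ks,
                      syn_substitutions = m_syn,
                      nonsyn_substitutions = m_nonsyn,
                      syn_sites = (S_anc + S_cur) / 2,
                      realized_ks = divergence))
}

# pick flanking bases that cannot extend a planted tandem run
ssr_with_breakers <- function(motif, repeats) {
  run <- strrep(motif, repeats)
  left <- setdiff(DNA_BASES, substr(motif, nchar(motif), nchar(motif)))[1]
  right <- setdiff(DNA_BASES, substr(motif, 1, 1))[1]
  list(run = run, left = left, right = right)
}

#' Simulate a gene-family genome package with planted ground truth
#'
#' Generates chromosomes, gene models, CDS and proteins; plants MYB repeats of
#' the configured classes, duplicate gene pairs evolved at chosen omega and
#' Ks, SSR loci in genic (intronic) or upstream regions; derives a partner
#' gene order with the configured rearrangements for synteny testing; and
#' simulates an expression count matrix with planted fold changes. Every
#' planted feature is recorded in a truth table. Deterministic under the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return An object of class `genome_package`: list with `chromosomes`
#'   (named DNA strings), `gene_models` (tibble: `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`; 1-based inclusive), `cds`, `proteins` (named
#'   vectors), `expression` (`counts`, `samples`, `gene_lengths`), `truth`
#'   (`planted_repeats`, `duplicate_truth`, `ssr_truth`, `de_truth`,
#'   `segment_truth`) and the `config`.
#' @export
simulate_family_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  profile <- myb_profile()
  n_chr <- config$n_chromosomes
  gpc <- config$genes_per_chromosome
  chroms <- sprintf("chr%02d", seq_len(n_chr))

  # --- base genes -----------------------------------------------------------
  total <- n_chr * gpc
  genes <- tibble(
    gene_id = sprintf("g%03d", seq_len(total)),
    chromosome = rep(chroms, each = gpc),
    slot = rep(seq_len(gpc), times = n_chr),
    myb_class = NA_character_)
  for (j in seq_along(config$myb_classes)) {
    chr_j <- ((j - 1) %% n_chr) + 1
    slot_j <- ((j - 1) %/% n_chr) + 1
    genes$myb_class[genes$chromosome == chroms[chr_j] &
                    genes$slot == slot_j] <- config$myb_classes[j]
  }

  cds <- character(total); names(cds) <- genes$gene_id
  proteins <- character(total); names(proteins) <- genes$gene_id
  planted_repeats <- list()
  for (i in seq_len(total)) {
    gid <- genes$gene_id[i]
    if (!is.na(genes$myb_class[i])) {
      syn <- synthesize_myb_protein(genes$myb_class[i],
                                    seed = child_seed(config$seed,
                                                      paste0("gene_", gid)),
                                    profile = profile)
      proteins[i] <- syn$protein
      cds[i] <- with_stream(config$seed, paste0("revtrans_", gid),
                            reverse_translate(syn$protein))
      planted_repeats[[gid]] <- dplyr::bind_cols(
        tibble(protein_id = gid, myb_class = genes$myb_class[i]), syn$repeats)
    } else {
      cds[i] <- with_stream(config$seed, paste0("gene_", gid), {
        L <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
        n_codon <- max(10, L %/% 3)
        sense <- names(genetic_code())[genetic_code() != "*"]
        body <- sample(sense, n_codon - 1, replace = TRUE)
        paste(c("ATG", body), collapse = "")
      })
      proteins[i] <- translate_cds(cds[i])
    }
  }

  # --- duplications ---------------------------------------------------------
  duplicate_truth <- list()
  dup_rows <- list()
  myb_ids <- genes$gene_id[!is.na(genes$myb_class)]
  source_pool <- if (length(myb_ids) > 0) myb_ids else genes$gene_id
  for (k in seq_along(config$duplication_events)) {
    ev <- config$duplication_events[[k]]
    src <- source_pool[(k - 1) %% length(source_pool) + 1]
    evolved <- evolve_duplicate_pair(
      cds[[src]], omega = ev$omega, target_ks = ev$target_ks,
      seed = child_seed(config$seed, paste0("dup_", k)))
    new_id <- paste0(src, "_d", k)
    cds[new_id] <- evolved$cds_b
    proteins[new_id] <- translate_cds(evolved$cds_b)
    src_chr <- genes$chromosome[genes$gene_id == src]
    if (ev$mode == "tandem") {
      place_chr <- src_chr
    } else if (n_chr > 1) {
      place_chr <- chroms[(match(src_chr, chroms) %% n_chr) + 1]
    } else {
      place_chr <- src_chr  # far placement enforced at assembly
    }
    dup_rows[[k]] <- tibble(gene_id = new_id, source = src, mode = ev$mode,
                            chromosome = place_chr)
    duplicate_truth[[k]] <- dplyr::bind_cols(
      tibble(gene_a = src, gene_b = new_id, mode = ev$mode), evolved$truth)
  }
  dup_tab <- dplyr::bind_rows(dup_rows)

  # --- SSR planting assignment ---------------------------------------------
  ssr_assign <- list()
  for (k in seq_along(config$ssr_plantings)) {
    sp <- config$ssr_plantings[[k]]
    gid <- genes$gene_id[(k - 1) %% total + 1]
    ssr_assign[[k]] <- c(list(gene_id = gid), sp)
  }

  # --- chromosome assembly --------------------------------------------------
  gene_models <- list()
  ssr_truth <- list()
  chrom_seqs <- setNames(character(n_chr), chroms)
  for (ci in seq_len(n_chr)) {
    chr <- chroms[ci]
    order_ids <- genes$gene_id[genes$chromosome == chr]
    # insert tandem duplicates right after their source; append segmental ones
    if (nrow(dup_tab) > 0) {
      for (r in seq_len(nrow(dup_tab))) {
        if (dup_tab$chromosome[r] != chr) next
        if (dup_tab$mode[r] == "tandem") {
          at <- match(dup_tab$source[r], order_ids)
          order_ids <- append(order_ids, dup_tab$gene_id[r], after = at)
        } else {
          order_ids <- c(order_ids, dup_tab$gene_id[r])
        }
      }
    }
    with_stream(config$seed, paste0("assembly_", chr), {
      pieces <- character(0)
      pos <- 0
      for (gid in order_ids) {
        plant <- purrr::detect(ssr_assign, ~ .x$gene_id == gid)
        is_dup <- grepl("_d\\d+$", gid)
        far_segmental <- is_dup && n_chr == 1 &&
          dup_tab$mode[match(gid, dup_tab$gene_id)] == "segmental"
        gap_len <- if (far_segmental) {
          150000L
        } else if (is_dup &&
                   dup_tab$mode[match(gid, dup_tab$gene_id)] == "tandem") {
          sample(200:2000, 1)
        } else {
          sample(config$intergenic_range[1]:config$intergenic_range[2], 1)
        }
        spacer <- random_dna(gap_len)
        if (!is.null(plant) && plant$region == "upstream") {
          ins <- ssr_with_breakers(plant$motif, plant$repeats)
          d_tss <- sample(50:800, 1)  # distance of run end from the TSS
          tail_len <- min(d_tss, gap_len - nchar(ins$run) - 2)
          head_len <- gap_len - tail_len - nchar(ins$run) - 2
          spacer <- paste0(substr(spacer, 1, max(0, head_len)), ins$left,
                           ins$run, ins$right,
                           substr(spacer, gap_len - tail_len + 1, gap_len))
          ssr_truth[[length(ssr_truth) + 1]] <- tibble(
            gene_id = gid, chromosome = chr, motif = plant$motif,
            repeats = plant$repeats, region = "upstream",
            start = pos + max(0, head_len) + 2,
            end = pos + max(0, head_len) + 1 + nchar(ins$run))
        }
        pieces <- c(pieces, spacer)
        pos <- pos + nchar(spacer)
        # genomic gene sequence; genic SSR plantings get an intron
        gene_cds <- paste0(cds[[gid]], "TAA")
        if (!is.null(plant) && plant$region == "genic") {
          ins <- ssr_with_breakers(plant$motif, plant$repeats)
          half <- (nchar(cds[[gid]]) %/% 6) * 3
          intron <- paste0(random_dna(60), ins$left, ins$run, ins$right,
                           random_dna(60))
          genomic <- paste0(substr(gene_cds, 1, half), intron,
                            substr(gene_cds, half + 1, nchar(gene_cds)))
          strand <- "+"
          ssr_truth[[length(ssr_truth) + 1]] <- tibble(
            gene_id = gid, chromosome = chr, motif = plant$motif,
            repeats = plant$repeats, region = "genic",
            start = pos + half + 62,
            end = pos + half + 61 + nchar(ins$run))
        } else {
          genomic <- gene_cds
          strand <- if (!is.null(plant)) "+" else sample(c("+", "-"), 1,
                                                         prob = c(0.7, 0.3))
          if (strand == "-") genomic <- reverse_complement(genomic)
        }
        gene_models[[length(gene_models) + 1]] <- tibble(
          gene_id = gid, chromosome = chr,
          start = pos + 1, end = pos + nchar(genomic), strand = strand)
        pieces <- c(pieces, genomic)
        pos <- pos + nchar(genomic)
      }
      pieces <- c(pieces, random_dna(
        sample(config$intergenic_range[1]:config$intergenic_range[2], 1)))
      chrom_seqs[chr] <- paste(pieces, collapse = "")
    })
    if (!is.null(config$chromosome_length) &&
        nchar(chrom_seqs[chr]) > config$chromosome_length) {
      stop("genes exceed chromosome capacity on ", chr, ": need ",
           nchar(chrom_seqs[chr]), " bp, capacity ",
           config$chromosome_length, " bp", call. = FALSE)
    }
  }
  gene_models <- dplyr::bind_rows(gene_models)

  # --- partner order / synteny truth ---------------------------------------
  segment_truth <- NULL
  if (length(config$rearrangements) > 0) {
    segment_truth <- simulate_anchor_genomes(
      gene_models = gene_models,
      rearrangements = config$rearrangements,
      seed = child_seed(config$seed, "rearrange"))
  }

  # --- expression -----------------------------------------------------------
  expr <- simulate_counts(config, gene_ids = gene_models$gene_id)
  expr$gene_lengths <- setNames(nchar(cds[gene_models$gene_id]),
                                gene_models$gene_id)

  structure(list(
    chromosomes = chrom_seqs,
    gene_models = gene_models,
    cds = cds,
    proteins = proteins,
    expression = expr[c("counts", "samples", "gene_lengths")],
    truth = list(
      planted_repeats = dplyr::bind_rows(planted_repeats),
      duplicate_truth = dplyr::bind_rows(duplicate_truth),
      ssr_truth = dplyr::bind_rows(ssr_truth),
      de_truth = expr$de_truth,
      segment_truth = segment_truth),
    config = config), class = "genome_package")
}

#' @export
print.genome_package <- function(x, ...) {
  cat("Synthetic genome package:", length(x$chromosomes), "chromosome(s),",
      nrow(x$gene_models), "gene(s)\n")
  cat("  planted MYB proteins:",
      length(unique(x$truth$planted_repeats$protein_id)),
      "| duplicate pairs:", nrow(x$truth$duplicate_truth),
      "| SSR loci:", nrow(x$truth$ssr_truth), "\n")
  invisible(x)
}

#' Simulate an anchor set for a genome pair with planted rearrangements
#'
#' Derives a partner gene order from a gene-model table (or an abstract gene
#' count) by applying inversions and translocations, and returns the
#' rank-level homolog anchors plus the resulting truth blocks (maximal runs
#' of collinear genes with orientation), the input the synteny chainer
#' consumes.
#'
#' @param gene_models Gene-model tibble (or `NULL` to build an abstract
#'   single-chromosome genome with `n_genes` genes).
#' @param n_genes Number of genes when `gene_models` is `NULL`.
#' @param rearrangements List of `list(type, span)`.
#' @param seed Integer seed.
#' @return A list with `anchors` (tibble: `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `rank_a`, `rank_b`) and `blocks` (tibble: `block_id`,
#'   `chrom_a`, `chrom_b`, `orientation`, `n_genes`, `gene_ids` list-column).
#' @export
simulate_anchor_genomes <- function(gene_models = NULL, n_genes = 30,
                                    rearrangements = list(), seed = 1L) {
  if (is.null(gene_models)) {
    gene_models <- tibble(gene_id = sprintf("g%03d", seq_len(n_genes)),
                          chromosome = "chr01",
                          start = seq_len(n_genes) * 1000,
                          end = seq_len(n_genes) * 1000 + 500,
                          strand = "+")
  }
  a_order <- gene_models %>%
    arrange(.data$chromosome, .data$start) %>%
    group_by(.data$chromosome) %>%
    mutate(rank_a = row_number() - 1L) %>%
    ungroup()
  # partner order starts as a collinear copy on matching chromosomes
  b_lists <- split(a_order$gene_id, a_order$chromosome)
  chrom_names <- names(b_lists)
  with_stream(seed, "partner_order", {
    for (rr in rearrangements) {
      span <- as.integer(rr$span)
      sizes <- vapply(b_lists, length, integer(1))
      eligible <- names(sizes)[sizes >= span]
      if (length(eligible) == 0) {
        stop("rearrangement span ", span, " exceeds every chromosome",
             call. = FALSE)
      }
      chr <- sample(eligible, 1)
      v <- b_lists[[chr]]
      at <- sample(seq_len(length(v) - span + 1), 1)
      block <- v[at:(at + span - 1)]
      if (rr$type == "inversion") {
        v[at:(at + span - 1)] <- rev(block)
        b_lists[[chr]] <- v
      } else {
        b_lists[[chr]] <- v[-(at:(at + span - 1))]
        dest_pool <- setdiff(chrom_names, chr)
        dest <- if (length(dest_pool) > 0) sample(dest_pool, 1) else chr
        b_lists[[dest]] <- c(b_lists[[dest]], block)
      }
    }
  })
  b_order <- dplyr::bind_rows(lapply(chrom_names, function(chr) {
    ids <- b_lists[[chr]]
    tibble(gene_id = ids, chrom_b = chr, rank_b = seq_along(ids) - 1L)
  }))
  anchors <- a_order %>%
    select(gene_id = "gene_id", chrom_a = "chromosome", rank_a = "rank_a") %>%
    left_join(b_order, by = "gene_id") %>%
    mutate(gene_a = .data$gene_id, gene_b = .data$gene_id) %>%
    select("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")
  blocks <- anchor_truth_blocks(anchors)
  list(anchors = anchors, blocks = blocks)
}

# truth blocks: maximal runs of anchors, within a chromosome pair, whose ranks
# advance in lockstep (step +1/+1 forward, +1/-1 reversed); a simple linear
# walk, independent of the DP chainer
anchor_truth_blocks <- function(anchors) {
  out <- list()
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b))) {
    sub <- anchors %>%
      filter(paste(.data$chrom_a, .data$chrom_b) == key) %>%
      arrange(.data$rank_a)
    i <- 1
    while (i <= nrow(sub)) {
      j <- i
      dir <- 0L
      while (j < nrow(sub) &&
             sub$rank_a[j + 1] == sub$rank_a[j] + 1L) {
        step <- sub$rank_b[j + 1] - sub$rank_b[j]
        if (abs(step) != 1L || (dir != 0L && step != dir)) break
        dir <- step
        j <- j + 1
      }
      out[[length(out) + 1]] <- tibble(
        chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
        orientation = if (dir < 0) "reversed" else "forward",
        n_genes = j - i + 1L,
        gene_ids = list(sub$gene_a[i:j]))
      i <- j + 1
    }
  }
  dplyr::bind_rows(out) %>%
    mutate(block_id = row_number()) %>%
    select("block_id", dplyr::everything())
}
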