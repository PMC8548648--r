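test_that("local protein alignment reports identity and coverage correctly", {
  a <- "MKVLLDTTAGHRSEW"
  self <- align_protein_pair(a, a)
  expect_equal(self$identity, 1)
  expect_equal(self$coverage, 1)
  # hand alignment: MKV vs MKI aligns M and K; identity over aligned columns
  hand <- align_protein_pair("MKV", "MKI")
  expect_equal(hand$identity * (nchar(hand$aligned_a)), 2)
  # unrelated random pairs rarely reach duplicate-level coverage
  set.seed(14)
  cov <- vapply(1:100, function(i) {
    align_protein_pair(random_protein_str(200),
                       random_protein_str(200))$coverage
  }, numeric(1))
  expect_gte(sum(cov < 0.75), 99)
})

test_that("duplicate-pair discovery applies strict identity/coverage screens", {
  gm <- tibble::tibble(gene_id = c("a", "b", "c"),
                       chromosome = "chr01",
                       start = c(1000, 5000, 9000),
                       end = c(1900, 5900, 9900), strand = "+")
  one <- tibble::tibble(gene_id = "a", protein = "MKVLLDTTAGHRSEW")
  expect_equal(nrow(find_duplicate_pairs(one, gm)), 0)
  expect_error(
    find_duplicate_pairs(
      tibble::tibble(gene_id = "zz", protein = "MKV"), gm),
    "no gene model")
  # identical pair passes; a pair at identity exactly the threshold would be
  # excluded by the strict inequality (checked via the filter rule itself)
  set.seed(3)
  p <- random_protein_str(120)
  prot <- tibble::tibble(gene_id = c("a", "b", "c"),
                         protein = c(p, p, random_protein_str(120)))
  pairs <- find_duplicate_pairs(prot, gm)
  expect_equal(nrow(pairs), 1)
  expect_identical(c(pairs$gene_a, pairs$gene_b), c("a", "b"))
  cfg <- evol_config(identity_min = 1.0)  # strict >: even 1.0 is excluded
  expect_equal(nrow(find_duplicate_pairs(prot, gm, cfg)), 0)
})

test_that("a planted duplicate pair is recovered end to end", {
  cfg <- simulation_config(
    seed = 11,
    duplication_events = list(list(mode = "tandem", omega = 0.2,
                                   target_ks = 0.5)))
  g <- simulate_family_genome(cfg)
  proteome <- tibble::tibble(gene_id = names(g$proteins),
                             protein = unname(g$proteins),
                             cds = unname(g$cds))
  dup <- characterize_duplicates(proteome, g$gene_models)
  tr <- g$truth$duplicate_truth
  row <- dup[dup$gene_a == tr$gene_a & dup$gene_b == tr$gene_b, ]
  expect_equal(nrow(row), 1)
  expect_identical(row$mode, "tandem")
  expect_equal(row$Ks, 0.5, tolerance = 0.2)
  expect_identical(row$selection, "purifying")
  expect_equal(row$T_mya, divergence_time(row$Ks))
})

test_that("tandem/segmental classification follows the 100-kb same-chromosome rule", {
  gm <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    chromosome = c("chr01", "chr01", "chr01", "chr02"),
    start = c(1000, 52000, 210000, 1000),
    end = c(2000, 53000, 211000, 2000), strand = "+")
  pairs <- tibble::tibble(gene_a = c("a", "a", "a"),
                          gene_b = c("b", "c", "d"))
  cls <- classify_duplication(pairs, gm)
  # gaps: 49,999 bp -> tandem; 207,999 bp -> segmental; cross-chromosome ->
  # segmental
  expect_identical(cls$mode, c("tandem", "segmental", "segmental"))
  # exactly 100 kb is segmental (strict <)
  gm2 <- gm; gm2$start[2] <- 102001; gm2$end[2] <- 103000
  cls2 <- classify_duplication(pairs[1, ], gm2)
  expect_equal(cls2$distance, 1e5)
  expect_identical(cls2$mode, "segmental")
})

test_that("codon alignment back-translates the protein alignment", {
  cds_a <- "ATGAAAGTT"          # MKV
  cds_b <- "ATGAAAATT"          # MKI
  aln <- list(aligned_a = "MKV", aligned_b = "MKI")
  ca <- codon_align(aln, cds_a, cds_b)
  expect_identical(ca$codon_a, c("ATG", "AAA", "GTT"))
  expect_identical(ca$codon_b, c("ATG", "AAA", "ATT"))
  # a gap column becomes a codon gap
  ca2 <- codon_align(list(aligned_a = "MKV", aligned_b = "M-V"),
                     "ATGAAAGTT", "ATGGTA")
  expect_identical(ca2$codon_b, c("ATG", "---", "GTA"))
  expect_error(codon_align(list(aligned_a = "MKV", aligned_b = "MKM"),
                           cds_a, cds_b), "does not match")
  # round trip on evolved pairs through the full aligner
  set.seed(6)
  for (i in 1:5) {
    cds <- paste(random_sense_codons(80), collapse = "")
    ev <- evolve_duplicate_pair(cds, omega = 0.3, target_ks = 0.3,
                                seed = 100 + i)
    pa <- translate_cds(ev$cds_a); pb <- translate_cds(ev$cds_b)
    al <- align_protein_pair(pa, pb)
    ca <- codon_align(al, ev$cds_a, ev$cds_b)
    re_a <- translate_cds(paste(ca$codon_a[ca$codon_a != "---"],
                                collapse = ""))
    expect_identical(re_a, paste(gsub("-", "", al$aligned_a), collapse = ""))
  }
})

test_that("NG86 matches the exhaustive enumeration oracle on small inputs", {
  # identical CDS: Ka = Ks = 0, omega undefined
  aln <- tibble::tibble(codon_a = c("ATG", "AAA"), codon_b = c("ATG", "AAA"))
  r <- ng86_ka_ks(aln)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$omega))
  # one synonymous third-position change in 30 codons: Ka 0, Ks from the
  # site-count oracle
  set.seed(19)
  a <- random_sense_codons(30)
  b <- a
  b[7] <- "GGA"; a[7] <- "GGG"  # synonymous glycine change
  r2 <- ng86_ka_ks(tibble::tibble(codon_a = a, codon_b = b))
  o2 <- oracle_ng86(a, b)
  expect_equal(r2$Ka, 0)
  expect_equal(r2$Ks, -0.75 * log(1 - 4 / (3 * o2$S)), tolerance = 1e-12)
  # random small cases against the oracle
  set.seed(23)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    a <- random_sense_codons(n)
    b <- a
    nmut <- sample(1:(2 * n), 1)
    for (k in seq_len(nmut)) {
      j <- sample(n, 1)
      cand <- random_sense_codons(1)
      b[j] <- cand
    }
    r <- suppressWarnings(ng86_ka_ks(tibble::tibble(codon_a = a, codon_b = b)))
    o <- oracle_ng86(a, b)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
  }
  # symmetry
  set.seed(29)
  a <- random_sense_codons(12); b <- random_sense_codons(12)
  r_ab <- suppressWarnings(ng86_ka_ks(tibble::tibble(codon_a = a, codon_b = b)))
  r_ba <- suppressWarnings(ng86_ka_ks(tibble::tibble(codon_a = b, codon_b = a)))
  expect_equal(r_ab$Sd, r_ba$Sd, tolerance = 1e-12)
  expect_equal(r_ab$Nd, r_ba$Nd, tolerance = 1e-12)
  expect_equal(r_ab$S, r_ba$S, tolerance = 1e-12)
})

test_that("divergence time is linear in Ks and matches printed examples", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.526), 37.79, tolerance = 1e-3)
  expect_equal(divergence_time(4.312), 309.77, tolerance = 1e-3)
  ks <- c(0.1, 0.5, 2)
  expect_equal(divergence_time(3 * ks), 3 * divergence_time(ks))
  expect_true(is.na(divergence_time(NA_real_)))
})

test_that("selection classification respects the neutral band", {
  expect_identical(classify_selection(0.25), "purifying")
  expect_identical(classify_selection(1.027), "positive")
  expect_identical(classify_selection(1.0), "neutral")
  expect_identical(classify_selection(NA_real_), NA_character_)
  wide <- evol_config(neutral_band = c(0.8, 1.2))
  expect_identical(classify_selection(1.1, wide), "neutral")
})

test_that("QTL co-localization uses containment on matching chromosomes", {
  gm <- tibble::tibble(gene_id = c("in1", "straddle", "off"),
                       chromosome = c("chr01", "chr01", "chr02"),
                       start = c(100, 450, 100),
                       end = c(200, 600, 200), strand = "+")
  qtl <- tibble::tibble(chromosome = "chr01", start = 50, end = 500,
                        trait = "capsaicin", qtl = "qtl-1")
  hit <- qtl_colocalize(gm, qtl)
  expect_identical(hit$gene_id, "in1")
  relaxed <- qtl_colocalize(gm, qtl, any_overlap = TRUE)
  expect_setequal(relaxed$gene_id, c("in1", "straddle"))
  expect_error(
    qtl_colocalize(gm, tibble::tibble(chromosome = "chrXX", start = 1,
                                      end = 10)),
    "unknown chromosome")
  # truth round-trip on a synthetic genome: QTL drawn around planted genes
  g <- simulate_family_genome(simulation_config(seed = 2))
  gm2 <- g$gene_models
  inside <- gm2[c(2, 5, 8), ]
  qtl2 <- tibble::tibble(chromosome = inside$chromosome,
                         start = inside$start - 10,
                         end = inside$end + 10,
                         qtl = paste0("q", 1:3))
  hits <- qtl_colocalize(gm2, qtl2)
  expect_setequal(hits$gene_id, inside$gene_id)
})
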