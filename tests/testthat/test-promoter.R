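test_that("upstream extraction is strand-aware and clipped", {
  genome <- c(chr01 = paste(rep("ACGT", 1000), collapse = ""))  # 4000 bp
  gm <- tibble::tibble(gene_id = c("plus", "minus", "edge"),
                       chromosome = "chr01",
                       start = c(2001, 501, 100),
                       end = c(2500, 1000, 180),
                       strand = c("+", "-", "+"))
  up <- extract_upstream(gm, genome, length = 1500)
  expect_equal(up$length[1], 1500)
  expect_identical(up$sequence[1], substr(genome[[1]], 501, 2000))
  # minus strand: reverse complement of the bases after the gene end
  expect_identical(up$sequence[2],
                   reverse_complement(substr(genome[[1]], 1001, 2500)))
  # truncation at the chromosome start
  expect_equal(up$length[3], 99)
  expect_true(up$truncated[3])
  expect_error(extract_upstream(
    tibble::tibble(gene_id = "x", chromosome = "chrZZ", start = 1, end = 9,
                   strand = "+"), genome), "not in genome")
})

test_that("SSR detection enforces thresholds, maximality and period minimality", {
  set.seed(61)
  flank1 <- "GCTCAGGCTTCGAACTGGACTTCAGGACTCGGATCGGACCTGAGGATCGC"
  flank2 <- "CAGGTCCTTGAGCAATCGGTACCAGTCGCATCAGGTACCGGATGACATCG"
  # the published extreme case: one hexanucleotide ATTTTA x 7 locus
  seq1 <- paste0(flank1, strrep("ATTTTA", 7), flank2)
  hit <- find_ssrs(c(x = seq1))
  expect_equal(nrow(hit), 1)
  expect_identical(hit$motif, "ATTTTA")
  expect_equal(hit$repeats, 7)
  expect_equal(hit$end - hit$start + 1, 42)
  # below the minimum repeat count: nothing
  expect_equal(nrow(find_ssrs(c(x = paste0(flank1, strrep("AT", 5),
                                           flank2)))), 0)
  # (AT)x6 is reported as AT x 6, never as ATAT x 3 (period minimality)
  hit2 <- find_ssrs(c(x = paste0(flank1, strrep("AT", 6), flank2)))
  expect_equal(nrow(hit2), 1)
  expect_identical(hit2$motif, "AT")
  # no run can be extended by one motif copy in either direction
  s <- paste0(flank1, strrep("CAG", 8), flank2)
  hit3 <- find_ssrs(c(x = s), min_repeats = 6)
  expect_equal(nrow(hit3), 1)
  expect_false(substr(s, hit3$start - 3, hit3$start - 1) == hit3$motif)
  expect_false(substr(s, hit3$end + 1, hit3$end + 3) == hit3$motif)
  # N breaks runs and never appears inside a locus
  expect_equal(nrow(find_ssrs(c(x = paste0(strrep("AT", 3), "N",
                                           strrep("AT", 3))))), 0)
  expect_error(find_ssrs(c(x = "ACGTQ")), "invalid base")
})

test_that("SSR detection equals the quadratic brute-force scanner", {
  set.seed(67)
  for (i in 1:25) {
    # repeat-enriched random sequences: random background with planted runs
    bg <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                collapse = "")
    ins <- paste0(strrep(sample(c("AT", "AAG", "ATTTTA", "CT", "GATA"), 1),
                         sample(5:9, 1)))
    at <- sample(100:600, 1)
    s <- paste0(substr(bg, 1, at), ins, substr(bg, at + 1, 800))
    got <- find_ssrs(c(q = s))
    want <- oracle_find_ssrs(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      o1 <- got[order(got$start, got$motif), ]
      o2 <- want[order(want$start, want$motif), ]
      expect_equal(o1$start, o2$start)
      expect_identical(o1$motif, o2$motif)
      expect_equal(o1$repeats, o2$repeats)
    }
  }
})

test_that("SSR summaries tally periods and break ties lexicographically", {
  empty <- summarize_ssrs(find_ssrs(c(x = "ACGTACGGGCA")))
  expect_equal(empty$n_loci, 0)
  expect_equal(empty$n_period_2, 0)
  loci <- tibble::tibble(
    sequence_id = "x",
    motif = c(rep("AT", 7), rep("AAG", 3)),
    repeats = c(rep(6, 7), rep(7, 3)),
    start = 1:10, end = 1:10)
  s <- summarize_ssrs(loci)
  expect_equal(s$dinucleotide_share, 70.0)
  expect_identical(s$modal_motif, "AT")
  expect_identical(s$longest_motif, "AAG")  # 3 x 7 = 21 beats 2 x 6 = 12
  # modal tie -> lexicographically smallest motif
  tie <- tibble::tibble(sequence_id = "x", motif = c("GA", "AT"),
                        repeats = c(6, 6), start = 1:2, end = 1:2)
  expect_identical(summarize_ssrs(tie)$modal_motif, "AT")
})

test_that("planted genome SSRs are recovered in the right regions", {
  cfg <- simulation_config(
    seed = 5,
    ssr_plantings = list(list(motif = "AT", repeats = 8, region = "upstream"),
                         list(motif = "AAG", repeats = 7, region = "genic")))
  g <- simulate_family_genome(cfg)
  found <- scan_gene_ssrs(g$chromosomes, g$gene_models, upstream = 1500)
  for (i in seq_len(nrow(g$truth$ssr_truth))) {
    tr <- g$truth$ssr_truth[i, ]
    match <- found[found$sequence_id == tr$gene_id &
                   found$region == tr$region &
                   found$motif == tr$motif, ]
    expect_gte(nrow(match), 1)
    expect_true(any(match$repeats >= tr$repeats))
  }
})

test_that("cis-element scanning matches IUPAC consensus on both strands", {
  dict <- tibble::tibble(element_name = "TATA-box", consensus = "TATAAA")
  hit <- scan_cis_elements("TATAAA", dict)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$position, 1)
  expect_identical(hit$strand, "+")
  # palindromic consensus: identical hit count on a sequence and its
  # reverse complement
  gbox <- tibble::tibble(element_name = "G-box", consensus = "CACGTG")
  s <- "GGGCACGTGTTTACGCACGTGAA"
  h1 <- scan_cis_elements(s, gbox)
  h2 <- scan_cis_elements(reverse_complement(s), gbox)
  expect_equal(nrow(h1), nrow(h2))
  # ambiguity codes: WGATAR matches AGATAA and TGATAG
  amb <- tibble::tibble(element_name = "GATA-motif", consensus = "WGATAR")
  h3 <- scan_cis_elements("CCAGATAACCTGATAGCC", amb)
  expect_equal(sum(h3$strand == "+"), 2)
  # dictionary order does not change the hit set
  set.seed(71)
  s2 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  d <- cis_element_dictionary()
  h_a <- scan_cis_elements(s2, d)
  h_b <- scan_cis_elements(s2, d[sample(nrow(d)), ])
  expect_identical(h_a, h_b)
  expect_error(
    scan_cis_elements("ACGT", tibble::tibble(element_name = "bad",
                                             consensus = "AC-GT")),
    "invalid IUPAC")
})
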