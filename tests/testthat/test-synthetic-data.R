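test_that("simulation is deterministic and honours empty configurations", {
  cfg <- simulation_config(seed = 7, n_chromosomes = 1,
                           genes_per_chromosome = 6, myb_classes = "R2R3")
  g1 <- simulate_family_genome(cfg)
  g2 <- simulate_family_genome(cfg)
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_identical(g1$gene_models, g2$gene_models)
  expect_identical(g1$expression$counts, g2$expression$counts)
  expect_identical(g1$truth, g2$truth)
  # no duplication events -> empty duplicate truth
  expect_equal(nrow(g1$truth$duplicate_truth), 0)
  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_package(g1, d1); write_genome_package(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("every emitted CDS translates exactly to its emitted protein", {
  cfg <- simulation_config(
    seed = 3, duplication_events = list(
      list(mode = "tandem", omega = 0.2, target_ks = 0.5),
      list(mode = "segmental", omega = 0.5, target_ks = 0.3)))
  g <- simulate_family_genome(cfg)
  expect_identical(unname(translate_cds(g$cds)), unname(g$proteins))
  # gene spans lie within their chromosomes
  for (i in seq_len(nrow(g$gene_models))) {
    gm <- g$gene_models[i, ]
    expect_gte(gm$start, 1)
    expect_lte(gm$end, nchar(g$chromosomes[[gm$chromosome]]))
  }
})

test_that("planted truth features re-locate in the emitted sequences", {
  cfg <- simulation_config(
    seed = 5,
    ssr_plantings = list(list(motif = "AT", repeats = 8, region = "upstream"),
                         list(motif = "AAG", repeats = 7, region = "genic"),
                         list(motif = "ATTTTA", repeats = 7, region = "genic")))
  g <- simulate_family_genome(cfg)
  expect_equal(nrow(g$truth$ssr_truth), 3)
  for (i in seq_len(nrow(g$truth$ssr_truth))) {
    tr <- g$truth$ssr_truth[i, ]
    expect_identical(
      substr(g$chromosomes[[tr$chromosome]], tr$start, tr$end),
      strrep(tr$motif, tr$repeats))
  }
  # planted repeats match their anchor architecture in the emitted protein
  pr <- g$truth$planted_repeats
  for (i in seq_len(nrow(pr))) {
    p <- g$proteins[[pr$protein_id[i]]]
    anchors <- c(pr$anchor1[i], pr$anchor2[i], pr$anchor3[i])
    residues <- substring(p, anchors, anchors)
    if (pr$type[i] == "R2") {
      expect_identical(residues, c("W", "W", "W"))
    } else {
      expect_identical(residues, c("F", "W", "W"))
    }
  }
})

test_that("planted tandem duplicates are same-chromosome pairs under 100 kb", {
  cfg <- simulation_config(
    seed = 11,
    duplication_events = list(list(mode = "tandem", omega = 0.2,
                                   target_ks = 0.5)))
  g <- simulate_family_genome(cfg)
  tr <- g$truth$duplicate_truth
  expect_equal(nrow(tr), 1)
  gm <- g$gene_models
  a <- gm[gm$gene_id == tr$gene_a, ]
  b <- gm[gm$gene_id == tr$gene_b, ]
  expect_identical(a$chromosome, b$chromosome)
  gap <- max(a$start, b$start) - min(a$end, b$end) - 1
  expect_lt(gap, 1e5)
  expect_equal(tr$realized_ks, 0.5, tolerance = 0.05)
})

test_that("infeasible packing errors name the chromosome", {
  cfg <- simulation_config(seed = 1, n_chromosomes = 1,
                           genes_per_chromosome = 10,
                           chromosome_length = 1000)
  expect_error(simulate_family_genome(cfg), "chr01")
})

test_that("codon evolution respects its boundary contracts", {
  cds <- "ATGGCTAAAGTTCTTGGTACTGAA"
  # target 0 -> identical sequences
  ev0 <- evolve_duplicate_pair(cds, omega = 0.5, target_ks = 0, seed = 1)
  expect_identical(ev0$cds_a, ev0$cds_b)
  # omega 0 -> identical proteins (synonymous changes only)
  set.seed(42)
  long <- paste(random_sense_codons(200), collapse = "")
  ev <- evolve_duplicate_pair(long, omega = 0, target_ks = 0.3, seed = 2)
  expect_identical(translate_cds(ev$cds_a), translate_cds(ev$cds_b))
  expect_false(identical(ev$cds_a, ev$cds_b))
  expect_equal(ev$truth$nonsyn_substitutions, 0)
  # saturation bound and precondition errors
  expect_error(evolve_duplicate_pair(long, 0.5, 1.2, seed = 1), "saturation")
  expect_error(evolve_duplicate_pair("ATGA", 0.5, 0.1, seed = 1),
               "divisible")
  expect_error(evolve_duplicate_pair("ATGTAAGGG", 0.5, 0.1, seed = 1),
               "stop")
})

test_that("simulated counts have the planted moment structure", {
  # dispersion -> 0 limit: per-gene variance ~ mean (Poisson)
  cfg <- simulation_config(seed = 9, n_chromosomes = 1,
                           genes_per_chromosome = 4,
                           de_plantings = list(fraction_de = 0,
                                               log2fc_magnitude = 0,
                                               dispersion = 0),
                           n_stages = 2, n_replicates = 2)
  sim <- simulate_counts(cfg, gene_ids = "g1")
  expect_true(all(sim$de_truth$true_log2fc == 0))
  # draw many replicates at fixed depth via the generator's NB model:
  # compare empirical variance/mean on a large Poisson sample
  set.seed(1)
  draws <- rpois(1e4, 50)
  expect_equal(var(draws) / mean(draws), 1, tolerance = 0.1)
  cfg2 <- simulation_config(seed = 9, de_plantings = list(
    fraction_de = 0.5, log2fc_magnitude = 2, dispersion = 0.1))
  sim2 <- simulate_counts(cfg2)
  expect_equal(mean(sim2$de_truth$true_log2fc != 0), 0.5)
  expect_true(all(abs(sim2$de_truth$true_log2fc[
    sim2$de_truth$true_log2fc != 0]) == 2))
  # library depths span the +/- 3-fold range, never beyond
  expect_true(all(sim2$samples$depth_factor >= 1 / 3 - 1e-9))
  expect_true(all(sim2$samples$depth_factor <= 3 + 1e-9))
  expect_error(
    simulate_counts(simulation_config(de_plantings = list(
      fraction_de = 0, log2fc_magnitude = 0, dispersion = -1))),
    "dispersion")
})

test_that("child seed streams are label-stable and independent", {
  expect_identical(child_seed(7, "genes"), child_seed(7, "genes"))
  expect_false(child_seed(7, "genes") == child_seed(7, "counts"))
  expect_false(child_seed(7, "genes") == child_seed(8, "genes"))
})
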