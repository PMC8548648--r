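sim_counts_quick <- function(seed, n_genes = 400, fraction_de = 0,
                             lfc = 0, dispersion = 0.1, n_reps = 3) {
  cfg <- simulation_config(seed = seed, n_chromosomes = 1,
                           genes_per_chromosome = n_genes,
                           myb_classes = character(0),
                           de_plantings = list(fraction_de = fraction_de,
                                               log2fc_magnitude = lfc,
                                               dispersion = dispersion),
                           n_stages = 2, n_replicates = n_reps)
  simulate_counts(cfg)
}

test_that("TMM factors are 1 for identical libraries and undo pure scaling", {
  set.seed(81)
  base <- matrix(rnbinom(400 * 2, mu = 100, size = 10), ncol = 2,
                 dimnames = list(sprintf("g%d", 1:400), c("s1", "s2")))
  same <- cbind(base[, 1], base[, 1])
  colnames(same) <- c("s1", "s2")
  f_same <- tmm_factors(same)
  expect_equal(f_same$norm_factor, c(1, 1), tolerance = 1e-9)
  # sample 2 = 2 x sample 1: normalized means agree after factoring
  doubled <- cbind(s1 = base[, 1], s2 = 2 * base[, 1])
  f <- tmm_factors(doubled)
  eff <- f$lib_size * f$norm_factor
  norm <- sweep(doubled, 2, eff / mean(eff), "/")
  expect_equal(norm[, 1], norm[, 2], tolerance = 1e-6)
  expect_equal(exp(mean(log(f$norm_factor))), 1, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(s1 = base[, 1], s2 = 0 * base[, 1])),
               "all-zero")
})

test_that("TMM is robust to a minority of inflated genes and matches edgeR", {
  set.seed(83)
  mu <- rlnorm(2000, log(200), 1)
  clean <- cbind(s1 = rpois(2000, mu), s2 = rpois(2000, mu))
  rownames(clean) <- sprintf("g%d", 1:2000)
  inflated <- clean
  idx <- sample(2000, 100)  # 5% of genes 8-fold inflated in sample 2
  inflated[idx, 2] <- inflated[idx, 2] * 8
  f_clean <- tmm_factors(clean)
  f_infl <- tmm_factors(inflated)
  # the factor must absorb the composition shift: the effective library size
  # of the contaminated sample stays within 2% of its uncontaminated value,
  # so the majority of (clean) genes normalize identically
  eff_clean <- f_clean$lib_size * f_clean$norm_factor
  eff_infl <- f_infl$lib_size * f_infl$norm_factor
  expect_equal(eff_infl[2] / eff_infl[1], eff_clean[2] / eff_clean[1],
               tolerance = 0.02)
  # independent implementation cross-check (edgeR weights the M-values by
  # count-level rather than proportion-level precision, so agreement is
  # close but not exact)
  skip_if_not_installed("edgeR")
  eref <- edgeR::calcNormFactors(inflated, method = "TMM")
  f_ratio <- unname(f_infl$norm_factor) / unname(eref)
  expect_equal(f_ratio[1], f_ratio[2], tolerance = 0.01)
})

test_that("FPKM follows its defining formula", {
  counts <- matrix(c(100, 0), nrow = 2,
                   dimnames = list(c("a", "b"), "s1"))
  counts <- cbind(counts, s2 = c(100, 50))
  lens <- c(a = 1000, b = 2000)
  f <- tibble::tibble(sample = c("s1", "s2"),
                      lib_size = c(1e7, 1e7), norm_factor = c(1, 1))
  fp <- compute_fpkm(counts, lens, f)
  expect_equal(fp["a", "s1"], 10)
  expect_equal(fp["b", "s1"], 0)
  # doubling the length halves FPKM
  lens2 <- c(a = 2000, b = 2000)
  expect_equal(compute_fpkm(counts, lens2, f)["a", "s1"], 5)
  expect_error(compute_fpkm(counts, c(a = 1000), f), "missing gene length")
})

test_that("differential expression calls nothing on identical groups and
          honours the significance conjunction", {
  set.seed(85)
  m <- matrix(rnbinom(200 * 3, mu = 80, size = 10), ncol = 3)
  m <- cbind(m, m)
  dimnames(m) <- list(sprintf("g%d", 1:200),
                      c(paste0("A", 1:3), paste0("B", 1:3)))
  de <- differential_expression(m, rep(c("A", "B"), each = 3))
  expect_equal(sum(tidy(de)$significant), 0)
  expect_error(differential_expression(m[, 1:3], c("A", "A", "B")),
               "at least 2 replicates")
  # significance is exactly the stated conjunction
  sim <- sim_counts_quick(seed = 3, fraction_de = 0.2, lfc = 2)
  de2 <- differential_expression(sim$counts,
                                 sub("_.*", "", colnames(sim$counts)))
  t2 <- tidy(de2)
  expect_identical(t2$significant,
                   t2$adj_p < 0.01 & abs(t2$log2fc) > log2(1.5))
  g <- glance(de2)
  expect_equal(g$n_significant, g$n_up + g$n_down)
})

test_that("BH adjustment equals the direct step-up formula", {
  set.seed(87)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("ddCt relative expression follows the Livak formula", {
  tab <- tibble::tibble(
    gene = rep("x", 6),
    condition = rep(c("calibrator", "treated"), each = 3),
    replicate = rep(1:3, 2),
    ct_target = c(22, 22.2, 21.8, 20, 20.1, 19.9),
    ct_reference = rep(15, 6))
  out <- delta_delta_ct(tab, "calibrator")
  expect_equal(out$relative_expression[out$condition == "calibrator"], 1)
  expect_equal(out$ddct[out$condition == "treated"], -2)
  expect_equal(out$relative_expression[out$condition == "treated"], 4)
  expect_lt(out$p[out$condition == "treated"], 0.05)
  # shifting every Ct by a constant leaves relative expression unchanged
  shifted <- tab
  shifted$ct_target <- shifted$ct_target + 3
  shifted$ct_reference <- shifted$ct_reference + 3
  out2 <- delta_delta_ct(shifted, "calibrator")
  expect_equal(out2$relative_expression, out$relative_expression)
  expect_error(delta_delta_ct(tab[tab$condition != "calibrator", ],
                              "calibrator"), "not present")
  bad <- tab; bad$ct_reference[2] <- NA
  expect_error(delta_delta_ct(bad, "calibrator"), "missing reference")
})

test_that("co-expression clustering separates archetype profiles", {
  # identical profiles share a cluster; anticorrelated groups split at k = 2
  prof_up <- c(1, 2, 4, 8, 16, 32)
  prof_down <- rev(prof_up)
  m <- rbind(u1 = prof_up, u2 = prof_up * 3, d1 = prof_down,
             d2 = prof_down * 2, const = rep(4, 6))
  colnames(m) <- paste0("s", 1:6)
  cl <- coexpression_clusters(m, k = 2)
  t <- tidy(cl)
  expect_equal(t$cluster[t$gene_id == "u1"], t$cluster[t$gene_id == "u2"])
  expect_equal(t$cluster[t$gene_id == "d1"], t$cluster[t$gene_id == "d2"])
  expect_false(t$cluster[t$gene_id == "u1"] == t$cluster[t$gene_id == "d1"])
  expect_equal(t$cluster[t$gene_id == "const"], 0L)
  expect_equal(glance(cl)$n_clusters, 2)
  expect_error(coexpression_clusters(m, k = 10), "fewer")
  # three planted archetypes + noise recovered (adjusted Rand via confusion)
  set.seed(89)
  arch <- rbind(c(0, 2, 4, 6), c(6, 4, 2, 0), c(0, 6, 0, 6))
  truth <- rep(1:3, each = 30)
  x <- arch[truth, ] + matrix(rnorm(90 * 4, sd = 0.2), ncol = 4)
  x <- 2^x  # back to FPKM-like scale; clustering logs it again
  rownames(x) <- sprintf("g%d", 1:90)
  colnames(x) <- paste0("s", 1:4)
  cl3 <- coexpression_clusters(x, k = 3)
  conf <- table(truth, tidy(cl3)$cluster)
  expect_equal(sum(apply(conf, 1, max)), 90)  # perfect recovery up to label
})
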