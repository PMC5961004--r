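test_that("trend test matches the from-scratch contingency computation", {
  # identical dosage distributions: statistic 0, P = 1
  d <- c(rep(0, 4), rep(1, 4), rep(2, 4))
  ph <- rep(c("case", "control"), 6)
  tt <- trend_test(d, ph)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)

  # complete separation, 10 + 10
  d2 <- c(rep(2, 10), rep(0, 10))
  ph2 <- c(rep("case", 10), rep("control", 10))
  tt2 <- trend_test(d2, ph2)
  expect_equal(tt2$statistic, oracle_trend_chi2(d2, ph2 == "case"),
               tolerance = 1e-10)

  set.seed(301)
  for (k in 1:50) {
    d <- rbinom(40, 2, runif(1, 0.2, 0.8))
    ph <- ifelse(runif(40) < 0.5, "case", "control")
    if (length(unique(d)) < 2 || length(unique(ph)) < 2) next
    got <- trend_test(d, ph)
    expect_equal(got$statistic, oracle_trend_chi2(d, ph == "case"),
                 tolerance = 1e-10)
  }
  # monomorphic -> missing; no cases -> error
  expect_true(is.na(trend_test(rep(1, 10),
                               rep(c("case", "control"), 5))$statistic))
  expect_error(trend_test(0:1, c("control", "control")), "case")
})

test_that("trend-test P-values are calibrated under the permuted null", {
  set.seed(311)
  n <- 60
  ph <- rep(c("case", "control"), each = n / 2)
  pvals <- replicate(4000, {
    d <- rbinom(n, 2, 0.4)
    trend_test(d, sample(ph))$p
  })
  pvals <- pvals[!is.na(pvals)]
  # discrete statistic: check calibration at the usual operating points
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
  expect_lt(abs(mean(pvals < 0.2) - 0.2), 0.03)
  expect_lt(abs(mean(pvals) - 0.5), 0.03)
})

test_that("bonferroni caps, scales and preserves order", {
  expect_equal(bonferroni(c(0.01, 0.5))[1], 0.02)
  expect_equal(bonferroni(rep(0.9, 10)), rep(1, 10))
  expect_equal(bonferroni(0.73), 0.73)  # m = 1 identity
  set.seed(321)
  p <- runif(50)
  expect_false(is.unsorted(bonferroni(p)[order(p)]))  # order-preserving
  expect_error(bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("clumping collects exactly the linked significant neighbours", {
  set.seed(331)
  n <- 40
  # perfect-LD block of 5 sites + 5 independent sites
  block <- rbinom(n, 2, 0.5); block[1] <- 1L
  g <- rbind(matrix(rep(block, 5), 5, n, byrow = TRUE),
             matrix(rbinom(5 * n, 2, 0.5), 5, n))
  panel <- genotype_panel(rep("c1", 10),
                          c(1e4, 2e4, 3e4, 4e4, 5e4,
                            2e5, 3e5, 4e5, 5e5, 6e5),
                          rep("A", 10), rep("C", 10), g)
  ph <- ifelse(block >= 1, "case", "control")  # block drives the trait
  ss <- two_pop_sheet(n, 0)
  ss$phenotype <- ph
  assoc <- assoc_scan(panel, ss)
  cl <- clump(panel, assoc, flank = 1e5)
  expect_equal(nrow(cl$members), 5)
  expect_setequal(cl$members$site, 1:5)
  expect_true(cl$index_site %in% 1:5)

  # no neighbour qualifies -> singleton clump
  cl2 <- clump(panel, assoc, index_site = 8, flank = 5e4)
  expect_equal(cl2$members$site, 8)
})

test_that("EM phasing is exact without ambiguity and recovers simulated phase", {
  # all homozygous: unique phasing
  g <- matrix(c(0, 2, 0, 2, 2, 0), 3, 2, byrow = TRUE)
  ph <- em_phase(g)
  expect_true(ph$converged)
  expect_equal(sort(unique(as.vector(ph$assignment))),
               seq_along(ph$haplotypes))
  expect_equal(ph$haplotypes[ph$assignment[1, 1]], "01")

  # single heterozygous site: frequencies equal observed allele freqs
  g2 <- cbind(c(0, 1, 2, 1, 0))
  ph2 <- em_phase(g2)
  f_alt <- sum(g2) / (2 * nrow(g2))
  expect_equal(sort(ph2$freq), sort(c(1 - f_alt, f_alt)), tolerance = 1e-6)

  # 6-site block from the simulator: collapse then re-phase
  sim <- simulate_panel(sim_config(
    n_samples = c(wild = 14, egg = 14, meat = 14),
    contig_lengths = c(chr2 = 3e5), z_contig = NA,
    sweeps = list(), switch_rate_per_bp = 2e-6, missing_rate = 0,
    trait = list(chrom = "chr2", start = 1e5, end = 1.2e5,
                 penetrance = 0.9, phenocopy = 0.05)), seed = 341)
  tp <- sim$truth
  site_rows <- match(paste(tp$trait_sites$chrom, tp$trait_sites$pos),
                     paste(sim$panel$chrom, sim$panel$pos))
  pick <- site_rows[seq(1, length(site_rows), length.out = 6)]
  in_block <- match(pick, site_rows)
  g3 <- t(sim$panel$geno[pick, , drop = FALSE])
  ph3 <- em_phase(g3)
  truth_h <- rbind(t(tp$block_phase$hap1[in_block, ]),
                   t(tp$block_phase$hap2[in_block, ]))
  est_h <- do.call(rbind, lapply(seq_len(nrow(g3)), function(i) {
    rbind(as.integer(strsplit(ph3$haplotypes[ph3$assignment[i, 1]], "")[[1]]),
          as.integer(strsplit(ph3$haplotypes[ph3$assignment[i, 2]], "")[[1]]))
  }))
  truth_pairs <- lapply(seq_len(nrow(g3)), function(i) {
    rbind(tp$block_phase$hap1[in_block, i], tp$block_phase$hap2[in_block, i])
  })
  correct <- 0L
  for (i in seq_len(nrow(g3))) {
    est <- est_h[(2 * i - 1):(2 * i), , drop = FALSE]
    tru <- truth_pairs[[i]]
    ok <- (all(est[1, ] == tru[1, ]) && all(est[2, ] == tru[2, ])) ||
      (all(est[1, ] == tru[2, ]) && all(est[2, ] == tru[1, ]))
    correct <- correct + 2L * ok
  }
  expect_gte(correct / (2 * nrow(g3)), 0.95)
})

test_that("EM phasing input validation", {
  expect_error(em_phase(matrix(c(0, NA), 1, 2)), "missing")
  expect_error(em_phase(matrix(0, 2, 26)), "25")
  expect_error(em_phase(matrix(2, 1, 1), hemi = TRUE), "hemizygous")
})

test_that("haplotype permutation chi-square matches the 2x2 oracle", {
  # 10/0 vs 0/10 chromosomes x2: hand-computable 2x2 table
  fake_phase <- list(haplotypes = c("00", "11"), freq = c(0.5, 0.5),
                     assignment = rbind(matrix(1L, 10, 2),
                                        matrix(2L, 10, 2)))
  phen <- c(rep("case", 10), rep("control", 10))
  ht <- haplotype_permutation_test(fake_phase, phen, n_perm = 200,
                                   seed = 5)
  # 2x2 with all 20/0 margins: chi2 = N = 40
  expect_equal(ht$chi2, 40)
  expect_equal(ht$p_perm, 1 / 201)
  # invariant to haplotype relabeling
  fake2 <- fake_phase
  fake2$haplotypes <- c("11", "00")
  ht2 <- haplotype_permutation_test(fake2, phen, n_perm = 200, seed = 5)
  expect_equal(ht2$chi2, ht$chi2)
  expect_equal(ht2$p_perm, ht$p_perm)
  # fixed seed -> identical result
  ht3 <- haplotype_permutation_test(fake_phase, phen, n_perm = 200,
                                    seed = 5)
  expect_identical(ht$p_perm, ht3$p_perm)
  # degenerate table -> missing
  fake3 <- list(haplotypes = "00", freq = 1,
                assignment = matrix(1L, 20, 2))
  expect_true(is.na(haplotype_permutation_test(fake3, phen,
                                               n_perm = 10)$chi2))
})

test_that("the GWAS-to-haplotype pipeline finds the planted causal block", {
  sim <- simulate_panel(sim_config(
    n_samples = c(wild = 0, egg = 40, meat = 0)[c("egg")],
    contig_lengths = c(chr1 = 5e5, chr2 = 5e5), z_contig = NA,
    drift_F = c(egg = 0.02), sweeps = list(),
    switch_rate_per_bp = 2e-5, missing_rate = 0,
    trait = list(chrom = "chr2", start = 2e5, end = 2.2e5,
                 penetrance = 0.95, phenocopy = 0.02)), seed = 351)
  res <- haplotype_association(sim$panel, sim$samples, n_perm = 500,
                               seed = 9)
  expect_equal(res$clump$chrom, "chr2")
  idx_pos <- sim$panel$pos[res$clump$index_site]
  # index SNP within the planted block +- the clump flank
  expect_gte(idx_pos, 2e5 - 1e5)
  expect_lte(idx_pos, 2.2e5 + 1e5)
  expect_lt(res$test$p_perm, 0.05)
})
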