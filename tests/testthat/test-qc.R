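test_that("HWE exact test matches the brute-force enumeration oracle", {
  cases <- list(c(10, 5, 25), c(25, 10, 1), c(0, 10, 10), c(20, 0, 0),
                c(3, 3, 3))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle_hwe_exact(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  set.seed(221)
  for (k in 1:100) {
    n <- sample(5:60, 1)
    g <- rbinom(n, 2, runif(1, 0.05, 0.95))
    expect_equal(hwe_exact_test(sum(g == 1), sum(g == 2), sum(g == 0)),
                 oracle_hwe_exact(sum(g == 1), sum(g == 2), sum(g == 0)),
                 tolerance = 1e-10)
  }
  # gross violation: all heterozygous
  expect_lt(hwe_exact_test(30, 0, 0), 1e-4)
})

test_that("inbreeding F matches its literal transcription and limits", {
  set.seed(231)
  for (k in 1:60) {
    p <- random_panel(40, 8, miss = 0.1, seed = NULL)
    j <- sample.int(8, 1)
    expect_equal(inbreeding_f(p, j), oracle_inbreeding_f(p$geno, j),
                 tolerance = 1e-10)
  }
  # sample homozygous everywhere -> F = 1
  g <- cbind(c(0L, 2L, 0L, 2L), matrix(rbinom(16, 2, 0.5), 4, 4))
  g[1, 2] <- 1L
  p1 <- genotype_panel(rep("c1", 4), 1:4 * 10, rep("A", 4), rep("C", 4), g)
  expect_equal(inbreeding_f(p1, 1), 1)
})

test_that("sex check flags hemizygosity-discordant samples only", {
  # single breeding line, as in a case/control QC panel: the F statistic
  # is computed against cohort frequencies, so population structure must
  # not be conflated with hemizygosity
  sim <- simulate_panel(sim_config(
    n_samples = c(egg = 40), drift_F = c(egg = 0.02),
    contig_lengths = c(chr1 = 1e5, chrZ = 2e5),
    sweeps = list(), trait = NULL, missing_rate = 0.02), seed = 241)
  sc <- sex_check(sim$panel, sim$samples)
  expect_equal(sum(sc$flag), 0)  # no false flags over 40 samples

  # swap one declared sex: sample 1 is male (diploid Z, F ~ 0)
  ss2 <- sim$samples
  expect_equal(ss2$sex[1], "male")
  ss2$sex[1] <- "female"
  sc2 <- sex_check(sim$panel, ss2)
  expect_true(sc2$flag[1])
  expect_equal(sum(sc2$flag), 1)

  # unknown sex is never flagged
  ss3 <- sim$samples
  ss3$sex[2] <- "unknown"
  expect_false(sex_check(sim$panel, ss3)$flag[2])
  expect_error(sex_check(sim$panel, sim$samples, z_contig = "nope"),
               "no sites")
})

test_that("IBS matrix matches the per-pair loop oracle and its limits", {
  p <- random_panel(60, 6, miss = 0.1, seed = 251)
  ibs <- ibs_matrix(p)
  expect_true(isSymmetric(ibs))
  expect_equal(unname(diag(ibs)), rep(1, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(ibs[i, j], oracle_ibs_pair(p$geno[, i], p$geno[, j]),
                 tolerance = 1e-12)
  }
  # identical columns -> 1; opposite homozygotes -> 0
  g <- cbind(rep(0L, 10), rep(0L, 10), rep(2L, 10))
  g[1, ] <- c(1L, 1L, 1L)
  p2 <- genotype_panel(rep("c1", 10), 1:10, rep("A", 10), rep("C", 10), g)
  ibs2 <- ibs_matrix(p2)
  expect_equal(ibs2[1, 2], 1)
  expect_equal(ibs2[1, 3], 0.1)  # differs at 9 of 10 sites
})

test_that("snp_qc removes planted violations with correct primary reasons", {
  set.seed(261)
  n <- 40
  m <- 60
  p_freq <- runif(m, 0.25, 0.75)
  g <- matrix(rbinom(m * n, 2, rep(p_freq, n)), m, n)
  # site 5: MGR 3/40 = 0.075 > 0.05
  g[5, 1:3] <- NA
  # site 10: MAF 0.02
  g[10, ] <- 0L; g[10, 1] <- 1L  # freq 1/80 = 0.0125
  # site 15: gross HWE violation (all het)
  g[15, ] <- 1L
  panel <- genotype_panel(rep("c1", m), seq_len(m) * 100, rep("A", m),
                          rep("C", m), g)
  ss <- two_pop_sheet(20, 20)
  ss$phenotype <- rep(c("case", "control"), each = 20)
  res <- snp_qc(panel, ss)
  rem <- res$report$removed_sites
  expect_true(all(c(500, 1000, 1500) %in% rem$pos))
  expect_equal(rem$reason[rem$pos == 500], "missingness")
  expect_equal(rem$reason[rem$pos == 1000], "maf")
  expect_equal(rem$reason[rem$pos == 1500], "hwe")
  # report counts add up
  expect_equal(res$report$n_in,
               res$report$n_out + nrow(rem))
  # idempotence: re-running on the output removes nothing
  res2 <- snp_qc(res$panel, ss)
  expect_equal(nrow(res2$report$removed_sites), 0)
})

test_that("differential missingness is caught between cases and controls", {
  set.seed(271)
  n <- 60; m <- 20
  g <- matrix(rbinom(m * n, 2, 0.5), m, n)
  ss <- two_pop_sheet(30, 30)
  ss$phenotype <- rep(c("case", "control"), each = 30)
  g[3, 1:12] <- NA  # 40% missing in cases, 0 in controls; MGR 0.2
  # make site 3 fail differential missingness *before* plain MGR would
  panel <- genotype_panel(rep("c1", m), seq_len(m) * 10, rep("A", m),
                          rep("C", m), g)
  res <- snp_qc(panel, ss, mgr_max = 0.25)
  rem <- res$report$removed_sites
  expect_true(30 %in% rem$pos)
  expect_equal(rem$reason[rem$pos == 30], "differential_missingness")
  # t-test mode agrees on this gross case
  res_t <- snp_qc(panel, ss, mgr_max = 0.25, dm_method = "ttest")
  expect_true(30 %in% res_t$report$removed_sites$pos)
})

test_that("individual_qc removes duplicates, high-missing and sex swaps", {
  sim <- simulate_panel(sim_config(
    n_samples = c(egg = 30), drift_F = c(egg = 0.02),
    contig_lengths = c(chr1 = 2e5, chrZ = 1e5),
    sweeps = list(), trait = NULL, missing_rate = 0.01), seed = 281)
  panel <- sim$panel; ss <- sim$samples
  # duplicate: copy sample 4 into sample 5 (same population)
  panel$geno[, 5] <- panel$geno[, 4]
  panel$ploidy[, 5] <- panel$ploidy[, 4]
  ss$sex[5] <- ss$sex[4]
  # high missingness: sample 8 at 15%
  drop_calls <- sample.int(n_sites(panel), round(0.15 * n_sites(panel)))
  panel$geno[drop_calls, 8] <- NA
  # sex swap: sample 12
  ss$sex[12] <- setdiff(c("male", "female"), ss$sex[12])
  res <- individual_qc(panel, ss)
  rem <- res$report$removed_individuals
  expect_setequal(rem$sample_id, ss$sample_id[c(5, 8, 12)])
  expect_equal(rem$reason[rem$sample_id == ss$sample_id[12]],
               "sex_discordant")
  expect_equal(rem$reason[rem$sample_id == ss$sample_id[8]],
               "high_missing")
  expect_equal(rem$reason[rem$sample_id == ss$sample_id[5]], "related")
  # idempotent on its own output
  res2 <- individual_qc(res$panel, res$samples)
  expect_equal(nrow(res2$report$removed_individuals), 0)
})

test_that("centered kinship matches the outer-product oracle and is PSD", {
  for (seed in c(291, 292, 293)) {
    p <- random_panel(80, 7, miss = 0.05, seed = seed)
    K <- kinship_centered(p)
    expect_true(isSymmetric(K))
    expect_equal(unname(K), unname(oracle_kinship(p$geno)),
                 tolerance = 1e-10)
    expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  }
  # single site at p = 0.5: hand-computed outer product
  g <- matrix(c(0L, 1L, 2L, 1L), 1, 4)
  p1 <- genotype_panel("c1", 1, "A", "C", g)
  K1 <- kinship_centered(p1)
  x <- c(0, 1, 2, 1) - 1
  expect_equal(unname(K1), outer(x, x))
  # identical samples get identical rows
  g2 <- matrix(rbinom(40, 2, 0.5), 20, 2)
  g2 <- cbind(g2, g2[, 2])
  g2[1, ] <- c(0L, 1L, 1L)
  p2 <- genotype_panel(rep("c1", 20), 1:20, rep("A", 20), rep("C", 20), g2)
  K2 <- kinship_centered(p2)
  expect_equal(K2[2, ], K2[3, ], tolerance = 1e-12, ignore_attr = TRUE)
})
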