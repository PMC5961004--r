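test_that("neutral SFS sampling matches the 1/i spectrum", {
  set.seed(361)
  n <- 20
  cnt <- sample_site_frequencies(n, 1e5, "neutral")
  expect_true(all(cnt >= 1 & cnt <= n - 1))
  expected <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  gof <- stats::chisq.test(tabulate(cnt, n - 1), p = expected)
  expect_gt(gof$p.value, 0.001)
  # n = 2: only the singleton class exists
  expect_equal(sample_site_frequencies(2, 10), rep(1L, 10))
})

test_that("sweep SFS pushes mass to the boundary classes", {
  set.seed(371)
  n <- 20
  cnt <- sample_site_frequencies(n, 2e4, "sweep", skew = 1)
  expect_gte(mean(cnt %in% c(1L, n - 1L)), 0.8)
  # skew 0 reduces to neutral
  cnt0 <- sample_site_frequencies(n, 1e5, "sweep", skew = 0)
  expected <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  expect_gt(stats::chisq.test(tabulate(cnt0, n - 1),
                              p = expected)$p.value, 0.001)
})

test_that("simulator honours missing_rate and is seed-deterministic", {
  cfg <- sim_config(n_samples = c(wild = 4, egg = 4, meat = 4),
                    contig_lengths = c(chr1 = 1e5, chrZ = 5e4),
                    sweeps = list(), trait = NULL, missing_rate = 0)
  s1 <- simulate_panel(cfg, seed = 5)
  expect_false(anyNA(s1$panel$geno))
  s2 <- simulate_panel(cfg, seed = 5)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$samples, s2$samples)
  s3 <- simulate_panel(cfg, seed = 6)
  expect_false(identical(s1$panel$geno, s3$panel$geno))
  # two same-seed fixture writes are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(s1, d1); write_fixture(s2, d2)
  expect_identical(readLines(file.path(d1, "panel.vcf")),
                   readLines(file.path(d2, "panel.vcf")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})

test_that("females are hemizygous on Z and dosage respects ploidy", {
  sim <- simulate_panel(sim_config(
    n_samples = c(wild = 6, egg = 6, meat = 6),
    contig_lengths = c(chr1 = 5e4, chrZ = 5e4),
    sweeps = list(), trait = NULL), seed = 15)
  z <- sim$panel$chrom == "chrZ"
  fem <- sim$samples$sex == "female"
  expect_true(all(sim$panel$ploidy[z, fem] == 1L))
  expect_true(all(sim$panel$ploidy[!z, ] == 2L))
  gz <- sim$panel$geno[z, fem]
  expect_true(all(is.na(gz) | gz <= 1L))
})

test_that("planted sweeps reduce diversity by the configured factor", {
  # skew 0 isolates the fixation component: pi ratio ~ 1 - reduction
  red <- 0.6
  sim <- simulate_panel(sim_config(
    contig_lengths = c(chr1 = 2e6), z_contig = NA,
    sweeps = list(list(pop = "egg", chrom = "chr1", start = 0, end = 1e6,
                       reduction = red, sfs_skew = 0)),
    trait = NULL, missing_rate = 0), seed = 25)
  win <- make_windows(c(chr1 = 2e6), 5e4, 5e4)
  dv <- window_diversity(sim$panel, win, "egg", sim$samples)
  in_sw <- win$end <= 1e6
  ratio <- mean(dv$pi[in_sw]) / mean(dv$pi[!in_sw])
  expect_lt(abs(ratio - (1 - red)), 0.12)

  # neutral control: reduction 0 leaves ROD un-enriched in the interval
  sim0 <- simulate_panel(sim_config(
    contig_lengths = c(chr1 = 2e6), z_contig = NA,
    sweeps = list(list(pop = "egg", chrom = "chr1", start = 0, end = 1e6,
                       reduction = 0, sfs_skew = 0)),
    trait = NULL, missing_rate = 0), seed = 26)
  dv0 <- window_diversity(sim0$panel, win, "egg", sim0$samples)
  dw0 <- window_diversity(sim0$panel, win, "wild", sim0$samples)
  rod0 <- window_rod(dv0, dw0)$rod
  expect_lt(abs(mean(rod0[in_sw]) - mean(rod0[!in_sw])), 0.06)
})

test_that("sweep windows show lower Tajima's D than neutral windows", {
  sim <- simulate_panel(sim_config(
    contig_lengths = c(chr1 = 2e6), z_contig = NA,
    sweeps = list(list(pop = "egg", chrom = "chr1", start = 2e5, end = 8e5,
                       reduction = 0.7, sfs_skew = 0.7)),
    trait = NULL, missing_rate = 0), seed = 35)
  win <- make_windows(c(chr1 = 2e6), 1e5, 1e5)
  dv <- window_diversity(sim$panel, win, "egg", sim$samples)
  in_sw <- win$start >= 2e5 & win$end <= 8e5
  expect_lt(mean(dv$tajima_d[in_sw], na.rm = TRUE),
            mean(dv$tajima_d[!in_sw], na.rm = TRUE))
})

test_that("trait phenotypes follow carriage of the causal haplotype", {
  sim <- simulate_panel(sim_config(
    n_samples = c(wild = 20, egg = 20, meat = 20),
    contig_lengths = c(chr1 = 2e5), z_contig = NA, sweeps = list(),
    drift_F = c(wild = 0.01, egg = 0.01, meat = 0.01),
    missing_rate = 0,
    trait = list(chrom = "chr1", start = 5e4, end = 8e4,
                 penetrance = 1, phenocopy = 0)), seed = 45)
  expect_true(all(sim$samples$phenotype %in% c("case", "control")))
  carrier <- sim$truth$carrier
  expect_true(all(sim$samples$phenotype[carrier] == "case"))
  expect_true(all(sim$samples$phenotype[!carrier] == "control"))
  # causal dosage matches carriage
  causal_row <- which(sim$panel$pos == sim$truth$trait$pos)
  expect_equal(unname(sim$panel$geno[causal_row, ] >= 1), carrier)
})

test_that("sim_config validates intervals and rates", {
  expect_error(sim_config(sweeps = list(list(pop = "nope", chrom = "chr1",
                                             start = 0, end = 1e5,
                                             reduction = 0.5,
                                             sfs_skew = 0))), "pop")
  expect_error(sim_config(sweeps = list(list(pop = "egg", chrom = "chr1",
                                             start = 0, end = 9e9,
                                             reduction = 0.5,
                                             sfs_skew = 0))), "interval")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
})
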