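# Small fixture builders, independent of the package's simulator: direct
# binomial genotypes with optional missingness, one contig.

random_panel <- function(n_sites = 50, n_samp = 10, miss = 0,
                         chrom = "chr1", p = NULL, seed = NULL,
                         pos = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p)) p <- runif(n_sites, 0.05, 0.95)
  g <- matrix(rbinom(n_sites * n_samp, 2, rep(p, n_samp)),
              n_sites, n_samp)
  if (miss > 0) g[runif(length(g)) < miss] <- NA
  if (is.null(pos)) pos <- sort(sample.int(n_sites * 100, n_sites))
  genotype_panel(rep(chrom, n_sites), pos,
                 rep("A", n_sites), rep("C", n_sites), g,
                 sample_ids = sprintf("S%02d", seq_len(n_samp)))
}

two_pop_sheet <- function(n_a, n_b, pop_a = "popA", pop_b = "popB") {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n_a + n_b)),
    population = c(rep(pop_a, n_a), rep(pop_b, n_b)),
    sex = rep("male", n_a + n_b),
    phenotype = rep("missing", n_a + n_b),
    stringsAsFactors = FALSE)
}

# per-population dosage panel built from explicit allele frequencies
two_pop_panel <- function(p_a, p_b, n_a = 8, n_b = 10, seed = 1) {
  set.seed(seed)
  m <- length(p_a)
  ga <- matrix(rbinom(m * n_a, 2, rep(p_a, n_a)), m, n_a)
  gb <- matrix(rbinom(m * n_b, 2, rep(p_b, n_b)), m, n_b)
  genotype_panel(rep("chr1", m), seq_len(m) * 1000,
                 rep("A", m), rep("C", m), cbind(ga, gb),
                 sample_ids = sprintf("S%02d", seq_len(n_a + n_b)))
}
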