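#' Simulation configuration
#'
#' Defines the statistical structure of a simulated three-population
#' panel: per-population sample sizes, contig lengths with one
#' hemizygous Z, genome-wide scaled diversity, Balding-Nichols drift
#' per population, planted sweep intervals (fractional diversity loss
#' plus frequency-spectrum skew), founder-mosaic LD, uniform
#' missingness, and an optional haplotype-driven binary trait.
#'
#' @param n_samples named per-population sample counts (default
#'   `c(wild = 10, egg = 11, meat = 10)`).
#' @param contig_lengths named contig lengths in bp (default two 2-Mb
#'   autosomes and a 1-Mb Z).
#' @param z_contig hemizygous contig id (default `"chrZ"`; `NA` for
#'   all-autosome genomes).
#' @param theta_per_bp scaled diversity per bp (default 0.005, the
#'   order of wild-population pi in galliform resequencing panels).
#' @param drift_F named Balding-Nichols drift per population (default
#'   0.01 wild, 0.05 for each domesticated line, reproducing the
#'   wild > domesticated diversity ordering).
#' @param sweeps list of sweep specs, each
#'   `list(pop=, chrom=, start=, end=, reduction=, sfs_skew=)`:
#'   `reduction` is the fractional loss of diversity in the swept
#'   population (0 = none, plain drift; ROD against wild is about
#'   `reduction`), `sfs_skew` the boundary-class mass of the surviving
#'   sites' frequency spectrum. Defaults plant one sweep per
#'   domesticated population.
#' @param founder_pool_size founder haplotypes per population
#'   (default 30).
#' @param switch_rate_per_bp founder-mosaic switch rate inducing
#'   distance-decaying LD (default 1e-3: LD half-decay of a few
#'   hundred bp, the rapid-decay regime reported for high-diversity
#'   galliform populations).
#' @param missing_rate per-call missing probability (default 0.02).
#' @param trait `NULL`, or `list(chrom=, start=, end=, penetrance=,
#'   phenocopy=)`: carriage of the derived allele at the causal block
#'   site makes a sample a case with probability `penetrance`,
#'   non-carriers with probability `phenocopy`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(wild = 10, egg = 11, meat = 10),
                       contig_lengths = c(chr1 = 2e6, chr2 = 2e6, chrZ = 1e6),
                       z_contig = "chrZ",
                       theta_per_bp = 0.005,
                       drift_F = c(wild = 0.01, egg = 0.05, meat = 0.05),
                       sweeps = NULL,
                       founder_pool_size = 30L,
                       switch_rate_per_bp = 1e-3,
                       missing_rate = 0.02,
                       trait = list(chrom = "chr2", start = 1.6e6,
                                    end = 1.65e6, penetrance = 0.9,
                                    phenocopy = 0.05)) {
  pops <- names(n_samples)
  if (is.null(pops)) stop("n_samples must be named by population")
  if (!setequal(pops, names(drift_F))) {
    stop("drift_F must be named like n_samples")
  }
  if (is.null(sweeps)) {
    sweeps <- list()
    dom <- setdiff(pops, pops[which.min(drift_F)])
    autos <- setdiff(names(contig_lengths), z_contig)
    for (k in seq_along(dom)) {
      ctg <- autos[1 + (k - 1) %% length(autos)]
      sweeps[[k]] <- list(pop = dom[k], chrom = ctg,
                          start = 4e5 + (k - 1) * 6e5,
                          end = 4e5 + (k - 1) * 6e5 + 3e5,
                          reduction = 0.85, sfs_skew = 0.7)
    }
  }
  for (sw in sweeps) {
    if (!sw$pop %in% pops) stop("sweep pop not in n_samples")
    if (!sw$chrom %in% names(contig_lengths)) stop("sweep contig unknown")
    if (sw$start < 0 || sw$end > contig_lengths[[sw$chrom]] ||
        sw$end <= sw$start) stop("sweep interval outside contig")
    if (sw$reduction < 0 || sw$reduction > 1 ||
        sw$sfs_skew < 0 || sw$sfs_skew > 1) stop("sweep rates must be in [0,1]")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0,1]")
  if (any(drift_F < 0 | drift_F >= 1)) stop("drift_F in [0,1)")
  structure(list(n_samples = n_samples, contig_lengths = contig_lengths,
                 z_contig = z_contig, theta_per_bp = theta_per_bp,
                 drift_F = drift_F, sweeps = sweeps,
                 founder_pool_size = as.integer(founder_pool_size),
                 switch_rate_per_bp = switch_rate_per_bp,
                 missing_rate = missing_rate, trait = trait),
            class = "sim_config")
}

#' Sample derived-allele counts from a site-frequency spectrum
#'
#' Neutral model: count `i` drawn with probability proportional to
#' `1/i` over `1..n_chrom-1`, the standard equilibrium spectrum. Sweep
#' model: with probability `skew` a boundary class (singleton or
#' `(n-1)`-ton, equally likely), otherwise a background tilted toward
#' rare alleles, `P(i) ~ i^-(1+skew)`; at `skew = 0` this is the
#' neutral spectrum.
#'
#' @param n_chrom chromosomes sampled (>= 2).
#' @param n_sites number of sites.
#' @param model `"neutral"` or `"sweep"`.
#' @param skew sweep-spectrum distortion in `[0, 1]`.
#' @return integer vector of derived-allele counts in `1..n_chrom-1`.
#' @export
sample_site_frequencies <- function(n_chrom, n_sites,
                                    model = c("neutral", "sweep"),
                                    skew = 0) {
  model <- match.arg(model)
  if (n_chrom < 2) stop("n_chrom must be >= 2")
  if (n_chrom == 2L) return(rep(1L, n_sites))
  i <- seq_len(n_chrom - 1)
  if (model == "neutral") {
    return(sample(i, n_sites, replace = TRUE, prob = 1 / i))
  }
  boundary <- stats::runif(n_sites) < skew
  out <- integer(n_sites)
  out[boundary] <- sample(c(1L, n_chrom - 1L), sum(boundary), replace = TRUE)
  out[!boundary] <- sample(i, sum(!boundary), replace = TRUE,
                           prob = i^-(1 + skew))
  out
}

# Balding-Nichols population frequency around ancestral p with drift F
balding_nichols <- function(p, F) {
  if (F < 1e-12) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate a multi-population genotype panel
#'
#' Frequencies-first construction: an ancestral neutral spectrum per
#' site, per-population frequencies by Balding-Nichols drift, founder
#' haplotype pools carrying binomially sampled alleles, and sample
#' chromosomes as founder mosaics (exponential switch process) giving
#' distance-decaying LD. Within planted sweep intervals the swept
#' population's chromosomes share a fixed background: each site is
#' fixed with probability `reduction`, and surviving sites carry
#' sample-level counts drawn from the sweep spectrum. Females are
#' hemizygous (one chromosome) on the Z contig. A trait, if
#' configured, is driven by carriage of the derived allele at the
#' causal site of the trait block (the block site with pooled
#' frequency nearest 0.3).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list: `panel` (a [genotype_panel()], ploidy mask reflecting
#'   the true sex), `samples` (sample sheet: alternating sexes within
#'   population, phenotype from the trait model or `"missing"`), and
#'   `truth` (`sim_truth`: planted sweeps, drift, trait with causal
#'   site and per-sample carriage, true phase at the trait-block
#'   sites, seed).
#' @export
simulate_panel <- function(cfg = sim_config(), seed = 1L) {
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  pops <- names(cfg$n_samples)
  N <- sum(cfg$n_samples)
  pop_of <- rep(pops, times = cfg$n_samples)
  sample_id <- unlist(lapply(pops, function(p) {
    sprintf("%s_%02d", p, seq_len(cfg$n_samples[[p]]))
  }))
  sex <- unlist(lapply(cfg$n_samples, function(k) {
    rep_len(c("male", "female"), k)
  }))
  K <- cfg$founder_pool_size
  n_pool <- 2L * N

  chrom_all <- character(0); pos_all <- integer(0)
  geno <- NULL; ploidy <- NULL
  block_phase <- NULL; trait_sites <- NULL
  carrier <- rep(FALSE, N)
  causal <- NULL

  for (ctg in names(cfg$contig_lengths)) {
    L <- cfg$contig_lengths[[ctg]]
    is_z <- !is.na(cfg$z_contig) && ctg == cfg$z_contig
    # chromosome copies per sample on this contig
    n_copies <- if (is_z) ifelse(sex == "female", 1L, 2L) else rep(2L, N)
    n_chrom <- sum(n_copies)

    m <- round(L * cfg$theta_per_bp * sum(1 / seq_len(n_pool - 1)))
    pos <- sort(sample.int(L, m))
    p0 <- sample_site_frequencies(n_pool, m, "neutral") / n_pool

    # per-population haplotypes
    hap_by_pop <- list()
    for (pop in pops) {
      cols <- which(pop_of == pop)
      copies <- n_copies[cols]
      nh <- sum(copies)
      p_pop <- balding_nichols(p0, cfg$drift_F[[pop]])
      fc <- stats::rbinom(m, K, p_pop)
      # carriers are the leading founders of a permutation that evolves
      # by random transpositions along the contig: neighbouring sites
      # share (nested) carrier sets, which is what makes r2 decay with
      # distance instead of sitting at the 1/K floor
      founders <- matrix(0L, K, m)
      perm <- sample.int(K)
      for (j in seq_len(m)) {
        if (j > 1L) {
          n_swap <- stats::rpois(1, cfg$switch_rate_per_bp * K *
                                   (pos[j] - pos[j - 1L]))
          for (t in seq_len(min(n_swap, 3L * K))) {
            ij <- sample.int(K, 2L)
            perm[ij] <- perm[rev(ij)]
          }
        }
        if (fc[j] > 0L) founders[perm[seq_len(fc[j])], j] <- 1L
      }
      hap <- matrix(0L, nh, m)
      if (m >= 2) {
        switch_p <- 1 - exp(-cfg$switch_rate_per_bp * diff(pos))
        for (h in seq_len(nh)) {
          sw <- stats::runif(m - 1) < switch_p
          seg <- cumsum(c(1L, sw))
          f_seg <- sample.int(K, max(seg), replace = TRUE)
          hap[h, ] <- founders[cbind(f_seg[seg], seq_len(m))]
        }
      } else if (m == 1L) {
        hap[, 1] <- founders[sample.int(K, nh, replace = TRUE), 1]
      }
      # planted sweeps, hitchhiking-style: all but a few "escaped"
      # chromosomes descend from the swept haplotype. The escaped count
      # is the integer whose between-pair fraction best matches the
      # target pi ratio of (1 - reduction), so the planted reduction is
      # controlled rather than left to Bernoulli noise. Swept
      # chromosomes share one background allele per site; escaped
      # chromosomes keep their drifted mosaic alleles (surfacing as
      # rare variants); sfs_skew adds young mutations as singletons on
      # the swept background, deepening the rare-allele excess
      for (sw in cfg$sweeps) {
        if (sw$pop != pop || sw$chrom != ctg) next
        in_iv <- which(pos > sw$start & pos <= sw$end)
        if (!length(in_iv)) next
        n_sw_cand <- 0:nh
        ratio <- 1 - n_sw_cand * (n_sw_cand - 1) / (nh * (nh - 1))
        n_swept <- n_sw_cand[which.min(abs(ratio - (1 - sw$reduction)))]
        if (n_swept == 0L) next
        swept <- sample.int(nh, n_swept)
        b <- stats::rbinom(length(in_iv), 1, p0[in_iv])
        hap[swept, in_iv] <- rep(b, each = length(swept))
        new_mut <- which(stats::runif(length(in_iv)) <
                           sw$sfs_skew * (1 - sw$reduction))
        for (jj in new_mut) {
          hap[swept[sample.int(length(swept), 1L)], in_iv[jj]] <-
            1L - b[jj]
        }
      }
      hap_by_pop[[pop]] <- hap
    }

    # assemble genotypes
    g <- matrix(0L, m, N)
    pl <- matrix(2L, m, N)
    hap1 <- matrix(NA_integer_, m, N)
    hap2 <- matrix(NA_integer_, m, N)
    for (pop in pops) {
      cols <- which(pop_of == pop)
      hap <- hap_by_pop[[pop]]
      row <- 0L
      for (s in cols) {
        if (n_copies[s] == 2L) {
          h1 <- hap[row + 1L, ]; h2 <- hap[row + 2L, ]
          g[, s] <- h1 + h2
          hap1[, s] <- h1; hap2[, s] <- h2
          row <- row + 2L
        } else {
          h1 <- hap[row + 1L, ]
          g[, s] <- h1
          pl[, s] <- 1L
          hap1[, s] <- h1
          row <- row + 1L
        }
      }
    }

    # trait block on this contig
    tr <- cfg$trait
    if (!is.null(tr) && tr$chrom == ctg) {
      in_block <- which(pos > tr$start & pos <= tr$end)
      if (!length(in_block)) stop("trait block contains no site")
      freq <- rowSums(cbind(hap1[in_block, , drop = FALSE],
                            hap2[in_block, , drop = FALSE]),
                      na.rm = TRUE) /
        (N + sum(!is.na(hap2[in_block[1], ])))
      causal_j <- in_block[which.min(abs(freq - 0.3))]
      carrier <- (!is.na(hap1[causal_j, ]) & hap1[causal_j, ] == 1L) |
        (!is.na(hap2[causal_j, ]) & hap2[causal_j, ] == 1L)
      causal <- list(chrom = ctg, pos = pos[causal_j],
                     start = tr$start, end = tr$end,
                     penetrance = tr$penetrance, phenocopy = tr$phenocopy)
      trait_sites <- data.frame(chrom = ctg, pos = pos[in_block])
      block_phase <- list(hap1 = hap1[in_block, , drop = FALSE],
                          hap2 = hap2[in_block, , drop = FALSE])
    }

    chrom_all <- c(chrom_all, rep(ctg, m))
    pos_all <- c(pos_all, pos)
    geno <- rbind(geno, g)
    ploidy <- rbind(ploidy, pl)
  }

  # uniform missingness
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < cfg$missing_rate
    geno[mask] <- NA_integer_
  }

  phenotype <- rep("missing", N)
  if (!is.null(causal)) {
    p_case <- ifelse(carrier, causal$penetrance, causal$phenocopy)
    phenotype <- ifelse(stats::runif(N) < p_case, "case", "control")
  }

  samples <- data.frame(sample_id = sample_id, population = pop_of,
                        sex = sex, phenotype = phenotype,
                        stringsAsFactors = FALSE)
  panel <- genotype_panel(chrom_all, pos_all,
                          ref = rep("A", length(pos_all)),
                          alt = rep("G", length(pos_all)),
                          geno = geno, ploidy = ploidy,
                          sample_ids = sample_id)
  truth <- structure(list(
    seed = seed, theta_per_bp = cfg$theta_per_bp, drift_F = cfg$drift_F,
    sweeps = cfg$sweeps, trait = causal, carrier = carrier,
    trait_sites = trait_sites, block_phase = block_phase),
    class = "sim_truth")
  list(panel = panel, samples = samples, truth = truth)
}

#' Write a simulated panel as a plain-text fixture
#'
#' VCF + sample-sheet TSV + truth JSON, re-readable by [read_vcf()]
#' with exact dosage equality.
#'
#' @param sim output of [simulate_panel()].
#' @param dir output directory (created if needed).
#' @return named vector of the three file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "panel.vcf")
  tsv <- file.path(dir, "samples.tsv")
  js <- file.path(dir, "truth.json")
  write_vcf(sim$panel, vcf)
  write_sample_sheet(sim$samples, tsv)
  truth <- unclass(sim$truth)
  truth$block_phase <- lapply(truth$block_phase, function(mm) {
    if (is.null(mm)) NULL else apply(mm, 2, paste, collapse = "")
  })
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(vcf = vcf, samples = tsv, truth = js))
}
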