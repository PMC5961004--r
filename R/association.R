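#' Cochran-Armitage trend test at one site
#'
#' Trend in case proportion over dosage scores, the standard single-SNP
#' association screen for a binary trait (used here as the P-value
#' provider feeding clumping and haplotype testing).
#'
#' @param dosages dosage vector (`NA` = missing).
#' @param phenotype vector of `"case"` / `"control"` (others ignored).
#' @return list with `statistic` (chi-square, 1 df) and `p`; both `NA`
#'   for monomorphic or degenerate sites.
#' @export
trend_test <- function(dosages, phenotype) {
  use <- !is.na(dosages) & phenotype %in% c("case", "control")
  d <- dosages[use]
  y <- phenotype[use] == "case"
  if (!any(y) || all(y)) stop("need >= 1 case and >= 1 control")
  lev <- sort(unique(d))
  if (length(lev) < 2) return(list(statistic = NA_real_, p = NA_real_))
  x <- vapply(lev, function(l) sum(y & d == l), numeric(1))
  n <- vapply(lev, function(l) sum(d == l), numeric(1))
  tt <- suppressWarnings(stats::prop.trend.test(x, n, score = lev))
  stat <- unname(tt$statistic)
  if (!is.finite(stat)) return(list(statistic = NA_real_, p = NA_real_))
  list(statistic = stat, p = unname(tt$p.value))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with `m` the number of tests.
#'
#' @param p_values raw P-values in `[0, 1]`.
#' @return adjusted P-values.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Genome-wide single-SNP association scan
#'
#' [trend_test()] at every site with Bonferroni adjustment over the
#' sites actually tested.
#'
#' @param panel a [genotype_panel()].
#' @param samples sample sheet with case/control phenotypes.
#' @return data.frame: `site` (panel row), `chrom`, `pos`, `statistic`,
#'   `p_raw`, `p_adjusted`.
#' @export
assoc_scan <- function(panel, samples) {
  res <- lapply(seq_len(n_sites(panel)), function(i) {
    trend_test(panel$geno[i, ], samples$phenotype)
  })
  stat <- vapply(res, `[[`, numeric(1), "statistic")
  p <- vapply(res, `[[`, numeric(1), "p")
  m <- sum(!is.na(p))
  p_adj <- rep(NA_real_, length(p))
  p_adj[!is.na(p)] <- pmin(1, m * p[!is.na(p)])
  data.frame(site = seq_len(n_sites(panel)), chrom = panel$chrom,
             pos = panel$pos, statistic = stat, p_raw = p,
             p_adjusted = p_adj)
}

#' Clump SNPs around an index SNP
#'
#' Sites within `flank` bp of the index on the same contig that are in
#' high LD with it (`r2 > r2_min`) and significantly associated
#' (`p_adjusted < p_adj_max`) are grouped with the index into one
#' clump for haplotype analysis. The index SNP is always a member.
#'
#' @param panel a [genotype_panel()].
#' @param assoc output of [assoc_scan()].
#' @param index_site panel row of the index SNP; default: the
#'   minimum-`p_adjusted` site (ties: smaller position).
#' @param flank flank in bp on each side (default 100 kb).
#' @param r2_min LD threshold to the index (default 0.7).
#' @param p_adj_max adjusted-P threshold (default 0.01).
#' @return list of class `clump`: `index_site`, `chrom`, `region`
#'   (`c(start, end)`, 0-based half-open), `members` data.frame
#'   (`site`, `pos`, `r2`, `p_adjusted`).
#' @export
clump <- function(panel, assoc, index_site = NULL, flank = 1e5,
                  r2_min = 0.7, p_adj_max = 0.01) {
  if (is.null(index_site)) {
    ok <- which(!is.na(assoc$p_adjusted))
    if (!length(ok)) stop("no tested site to index on")
    best <- ok[order(assoc$p_adjusted[ok], assoc$pos[ok])][1]
    index_site <- assoc$site[best]
  }
  if (!index_site %in% assoc$site) stop("index_site not in assoc table")
  ipos <- panel$pos[index_site]
  ichr <- panel$chrom[index_site]
  cand <- which(panel$chrom == ichr & abs(panel$pos - ipos) <= flank)
  r2 <- vapply(cand, function(j) {
    if (j == index_site) return(1)
    r <- r2_pair(panel$geno[index_site, ], panel$geno[j, ])
    if (is.na(r)) 0 else r
  }, numeric(1))
  padj <- assoc$p_adjusted[match(cand, assoc$site)]
  member <- cand == index_site |
    (r2 > r2_min & !is.na(padj) & padj < p_adj_max)
  members <- data.frame(site = cand[member], pos = panel$pos[cand[member]],
                        r2 = r2[member], p_adjusted = padj[member])
  structure(list(index_site = index_site, chrom = ichr,
                 region = c(max(0, ipos - 1 - flank), ipos + flank),
                 members = members[order(members$pos), , drop = FALSE]),
            class = "clump")
}

#' Excoffier-Slatkin EM haplotype phasing
#'
#' Maximum-likelihood haplotype frequencies over the diplotype-
#' compatible haplotype pairs of each individual, by EM; each
#' individual is then assigned its maximum-posterior pair. Hemizygous
#' individuals carry a single, directly observed haplotype and
#' contribute one chromosome.
#'
#' @param g individuals x sites dosage matrix with no missing calls
#'   (exclude individuals with missing clump calls first); at most 25
#'   sites.
#' @param hemi logical per individual: `TRUE` for a single-chromosome
#'   (hemizygous) individual, whose dosages must be 0/1.
#' @param tol convergence tolerance on the largest frequency change
#'   (default 1e-6).
#' @param max_iter EM iteration cap; non-convergence is flagged and the
#'   best-so-far fit returned.
#' @return list: `haplotypes` (character, e.g. `"0101"`), `freq`,
#'   `assignment` (individuals x 2 haplotype indices, second `NA` for
#'   hemizygous), `loglik`, `converged`.
#' @export
em_phase <- function(g, hemi = NULL, tol = 1e-6, max_iter = 1000L) {
  g <- as.matrix(g)
  if (anyNA(g)) stop("missing calls in clump genotypes; exclude them first")
  if (ncol(g) > 25L) stop("at most 25 sites supported")
  n <- nrow(g)
  if (is.null(hemi)) hemi <- rep(FALSE, n)
  if (any(g[hemi, , drop = FALSE] > 1)) stop("hemizygous dosages must be 0/1")

  hap_key <- function(h) paste(h, collapse = "")
  # enumerate compatible (hap, hap) pairs per individual
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    if (hemi[i]) {
      pairs[[i]] <- list(list(a = hap_key(g[i, ]), b = NA_character_))
      next
    }
    het <- which(g[i, ] == 1L)
    base <- ifelse(g[i, ] == 2L, 1L, 0L)
    if (!length(het)) {
      pairs[[i]] <- list(list(a = hap_key(base), b = hap_key(base)))
    } else {
      if (length(het) > 16L) stop("too many heterozygous sites to enumerate")
      # fix the last het site's allele to break mirror symmetry
      combos <- if (length(het) == 1L) matrix(0L, 1, 1)
                else cbind(as.matrix(expand.grid(rep(list(0:1),
                                                     length(het) - 1L))), 0L)
      pairs[[i]] <- lapply(seq_len(nrow(combos)), function(k) {
        h1 <- base; h2 <- base
        h1[het] <- as.integer(combos[k, ])
        h2[het] <- 1L - h1[het]
        list(a = hap_key(h1), b = hap_key(h2))
      })
    }
  }
  haps <- sort(unique(unlist(lapply(pairs, function(pp)
    unlist(lapply(pp, function(q) c(q$a, q$b)))))))
  haps <- haps[!is.na(haps)]
  H <- length(haps)
  pa <- lapply(pairs, function(pp) match(vapply(pp, `[[`, character(1), "a"), haps))
  pb <- lapply(pairs, function(pp) {
    b <- vapply(pp, function(q) if (is.na(q$b)) NA_character_ else q$b, character(1))
    match(b, haps)
  })
  n_chrom <- sum(ifelse(hemi, 1L, 2L))

  f <- rep(1 / H, H)
  converged <- FALSE
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    for (i in seq_len(n)) {
      a <- pa[[i]]; b <- pb[[i]]
      if (hemi[i]) {
        counts[a] <- counts[a] + 1
        ll <- ll + log(max(f[a], 1e-300))
        next
      }
      w <- f[a] * f[b] * ifelse(a == b, 1, 2)
      tw <- sum(w)
      if (tw <= 0) { w <- rep(1 / length(w), length(w)); tw <- 1 }
      ll <- ll + log(max(tw, 1e-300))
      w <- w / tw
      for (k in seq_along(a)) {
        counts[a[k]] <- counts[a[k]] + w[k]
        counts[b[k]] <- counts[b[k]] + w[k]
      }
    }
    f_new <- counts / n_chrom
    delta <- max(abs(f_new - f))
    f <- f_new
    loglik <- ll
    if (delta < tol) { converged <- TRUE; break }
  }

  assignment <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    a <- pa[[i]]; b <- pb[[i]]
    if (hemi[i]) { assignment[i, 1] <- a[1]; next }
    w <- f[a] * f[b] * ifelse(a == b, 1, 2)
    k <- which.max(w)
    assignment[i, ] <- c(a[k], b[k])
  }
  list(haplotypes = haps, freq = f, assignment = assignment,
       loglik = loglik, converged = converged)
}

# chi-square statistic of a contingency table, no continuity correction
chi2_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- e > 0
  sum((tab[ok] - e[ok])^2 / e[ok])
}

#' Permutation chi-squared test of haplotype x phenotype association
#'
#' Chi-square on the haplotype-by-phenotype chromosome-count table
#' (haplotypes below `min_freq` pooled into `"other"`), with an
#' empirical P from phenotype-label permutations at the individual
#' level while the phase is held fixed:
#' `p_perm = (exceedances + 1) / (n_perm + 1)`.
#'
#' @param phase an [em_phase()] fit (or any list with `haplotypes`,
#'   `freq`, `assignment`).
#' @param phenotype per-individual `"case"` / `"control"`, aligned to
#'   the rows of `phase$assignment`.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed for the permutation stream.
#' @param min_freq pooling threshold on haplotype frequency
#'   (default 0.01).
#' @return list of class `haplotype_test`: `table` (counts), `chi2`,
#'   `p_perm`, `n_perm`, `seed`; `chi2`/`p_perm` are `NA` when the
#'   pooled table is degenerate.
#' @export
haplotype_permutation_test <- function(phase, phenotype, n_perm = 5000L,
                                       seed = NULL, min_freq = 0.01) {
  asg <- phase$assignment
  n <- nrow(asg)
  stopifnot(length(phenotype) == n)
  use <- phenotype %in% c("case", "control")
  asg <- asg[use, , drop = FALSE]
  phen <- phenotype[use]

  class_of <- ifelse(phase$freq[seq_along(phase$haplotypes)] < min_freq,
                     "other", phase$haplotypes)
  # chromosome-level expansion: individual index and haplotype class
  ind <- rep(seq_len(nrow(asg)), times = 2)[!is.na(as.vector(asg))]
  hap <- class_of[as.vector(asg)[!is.na(as.vector(asg))]]
  classes <- sort(unique(hap))
  if (length(classes) < 2 || length(unique(phen)) < 2) {
    return(structure(list(table = NULL, chi2 = NA_real_, p_perm = NA_real_,
                          n_perm = n_perm, seed = seed),
                     class = "haplotype_test"))
  }
  hap_i <- match(hap, classes)
  count_tab <- function(ph) {
    is_case <- ph[ind] == "case"
    rbind(case = tabulate(hap_i[is_case], length(classes)),
          control = tabulate(hap_i[!is_case], length(classes)))
  }
  obs_tab <- count_tab(phen)
  colnames(obs_tab) <- classes
  chi2 <- chi2_stat(obs_tab)

  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(restore_rng(rng))
  }
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(phen)
    if (chi2_stat(count_tab(perm)) >= chi2 - 1e-12) exceed <- exceed + 1L
  }
  structure(list(table = obs_tab, chi2 = chi2,
                 p_perm = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "haplotype_test")
}

#' @export
print.haplotype_test <- function(x, ...) {
  if (is.na(x$chi2)) {
    cat("haplotype test: degenerate table, undefined\n")
    return(invisible(x))
  }
  print(x$table)
  cat(sprintf("chi2 = %.3f, permutation P = %.4g (%d permutations)\n",
              x$chi2, x$p_perm, x$n_perm))
  invisible(x)
}

#' GWAS-to-haplotype pipeline for a case/control panel
#'
#' Runs the association scan, picks the index SNP (minimum adjusted P),
#' clumps, phases the clump by EM over individuals with complete calls,
#' and runs the permutation haplotype test.
#'
#' @param panel a [genotype_panel()] (post QC).
#' @param samples sample sheet with phenotypes.
#' @param flank,r2_min,p_adj_max clump parameters (see [clump()]).
#' @param n_perm,seed permutation-test parameters.
#' @return list: `assoc`, `clump`, `phase`, `test`.
#' @export
haplotype_association <- function(panel, samples, flank = 1e5,
                                  r2_min = 0.7, p_adj_max = 0.01,
                                  n_perm = 5000L, seed = NULL) {
  assoc <- assoc_scan(panel, samples)
  cl <- clump(panel, assoc, flank = flank, r2_min = r2_min,
              p_adj_max = p_adj_max)
  sites <- cl$members$site
  g <- t(panel$geno[sites, , drop = FALSE])
  hemi <- apply(panel$ploidy[sites, , drop = FALSE] == 1L, 2, any)
  complete <- !apply(is.na(g), 1, any)
  phase <- em_phase(g[complete, , drop = FALSE], hemi = hemi[complete])
  test <- haplotype_permutation_test(phase, samples$phenotype[complete],
                                     n_perm = n_perm, seed = seed)
  list(assoc = assoc, clump = cl, phase = phase, test = test,
       phased_samples = samples$sample_id[complete])
}
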