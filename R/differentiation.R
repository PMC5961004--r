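#' Weir-Cockerham variance components at biallelic sites
#'
#' The 1984 method-of-moments components for two populations: `a`
#' (among-population), `b` (among-individual within population) and `c`
#' (within-individual, i.e. half the heterozygote frequency). Per-site
#' FST is `a / (a + b + c)`; window estimates are ratios of sums.
#' Hemizygous calls enter as half an individual with zero heterozygosity,
#' which reduces to the standard diploid formulation when absent.
#'
#' @param alt_count length-2 (or 2-column matrix) alt-allele counts per
#'   population.
#' @param chrom_n length-2 (or 2-column matrix) non-missing chromosome
#'   counts per population (each >= 2).
#' @param het_count length-2 (or 2-column matrix) observed heterozygote
#'   call counts per population.
#' @return data.frame with columns `a`, `b`, `c` (one row per site).
#' @export
wc_site_components <- function(alt_count, chrom_n, het_count) {
  ac <- rbind(alt_count); cn <- rbind(chrom_n); hc <- rbind(het_count)
  if (ncol(ac) != 2L) stop("exactly 2 populations required")
  if (any(cn < 2)) stop("each population needs >= 2 chromosomes")
  r <- 2
  n1 <- cn[, 1] / 2; n2 <- cn[, 2] / 2      # individual-equivalents
  p1 <- ac[, 1] / cn[, 1]; p2 <- ac[, 2] / cn[, 2]
  h1 <- hc[, 1] / n1; h2 <- hc[, 2] / n2    # het proportions
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  data.frame(a = a, b = b, c = cc)
}

# per-site W&C components for a panel and two sample-column sets;
# rows with a fully-missing population are NA
wc_components_panel <- function(panel, cols_a, cols_b) {
  comp_pop <- function(cols) {
    g <- panel$geno[, cols, drop = FALSE]
    pl <- panel$ploidy[, cols, drop = FALSE]
    obs <- !is.na(g)
    list(alt = rowSums(g * obs, na.rm = TRUE),
         cn = rowSums(pl * obs),
         het = rowSums(obs & g == 1L & pl == 2L, na.rm = TRUE))
  }
  pa <- comp_pop(cols_a); pb <- comp_pop(cols_b)
  ok <- pa$cn >= 2 & pb$cn >= 2
  out <- data.frame(a = rep(NA_real_, n_sites(panel)), b = NA_real_,
                    c = NA_real_)
  if (any(ok)) {
    out[ok, ] <- wc_site_components(cbind(pa$alt, pb$alt)[ok, , drop = FALSE],
                                    cbind(pa$cn, pb$cn)[ok, , drop = FALSE],
                                    cbind(pa$het, pb$het)[ok, , drop = FALSE])
  }
  out$polymorphic <- ok & (pa$alt + pb$alt > 0) &
    (pa$alt + pb$alt < pa$cn + pb$cn)
  out
}

#' Sliding-window Weir-Cockerham FST
#'
#' Weighted (ratio-of-sums) estimator `sum(a) / sum(a+b+c)` over
#' polymorphic sites per window, the windowed default of the standard
#' VCF toolchain; a per-site-mean variant is available. Negative
#' estimates are reported as computed, not clamped.
#'
#' @param panel a [genotype_panel()].
#' @param windows window data.frame from [make_windows()].
#' @param pop_a,pop_b population labels.
#' @param samples sample sheet.
#' @param method `"weighted"` (default) or `"mean"` (mean of per-site
#'   ratios).
#' @return data.frame: window columns plus `pop_a`, `pop_b`, `fst`
#'   (`NA` when no polymorphic site) and `n_sites_used`.
#' @export
window_fst <- function(panel, windows, pop_a, pop_b, samples,
                       method = c("weighted", "mean")) {
  method <- match.arg(method)
  cols_a <- which(samples$population == pop_a)
  cols_b <- which(samples$population == pop_b)
  if (!length(cols_a) || !length(cols_b)) stop("unknown population label")
  comp <- wc_components_panel(panel, cols_a, cols_b)
  use <- comp$polymorphic & !is.na(comp$a)
  idx <- window_site_index(panel, windows)
  fst <- rep(NA_real_, nrow(windows))
  n_used <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    i <- idx[[w]][use[idx[[w]]]]
    n_used[w] <- length(i)
    if (!length(i)) next
    if (method == "weighted") {
      denom <- sum(comp$a[i] + comp$b[i] + comp$c[i])
      if (denom != 0) fst[w] <- sum(comp$a[i]) / denom
    } else {
      site <- comp$a[i] / (comp$a[i] + comp$b[i] + comp$c[i])
      fst[w] <- mean(site[is.finite(site)])
    }
  }
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, index = windows$index,
             pop_a = pop_a, pop_b = pop_b, fst = fst,
             n_sites_used = n_used)
}

#' Reduction of diversity (ROD)
#'
#' `ROD = 1 - pi_dom / pi_wild` per window: near 1 where the
#' domesticated population has lost the diversity the wild population
#' retains, 0 under equal diversity, negative where the domesticated
#' population is the more diverse.
#'
#' @param pi_dom,pi_wild per-window pi for the domesticated and wild
#'   populations, on identical windows.
#' @return numeric vector; `NA` where `pi_wild == 0`.
#' @export
rod <- function(pi_dom, pi_wild) {
  if (any(pi_dom < 0, na.rm = TRUE) || any(pi_wild < 0, na.rm = TRUE)) {
    stop("pi values must be non-negative")
  }
  out <- 1 - pi_dom / pi_wild
  out[!is.na(pi_wild) & pi_wild == 0] <- NA_real_
  out
}

#' Per-window ROD from two diversity tables
#'
#' @param div_dom,div_wild outputs of [window_diversity()] on the same
#'   window list for the domesticated and wild populations.
#' @return data.frame: window columns plus `rod`, `pi_dom`, `pi_wild`.
#' @export
window_rod <- function(div_dom, div_wild) {
  if (!identical(div_dom$index, div_wild$index)) {
    stop("diversity tables are not on the same window list")
  }
  data.frame(chrom = div_dom$chrom, start = div_dom$start,
             end = div_dom$end, index = div_dom$index,
             rod = rod(div_dom$pi, div_wild$pi),
             pi_dom = div_dom$pi, pi_wild = div_wild$pi)
}

#' Highly differentiated sites
#'
#' Per-site Weir-Cockerham FST `a/(a+b+c)` scanned against a threshold,
#' optionally restricted to an annotation label (e.g. non-synonymous
#' sites with FST > 0.5).
#'
#' @param panel a [genotype_panel()].
#' @param pop_a,pop_b population labels.
#' @param samples sample sheet.
#' @param threshold FST threshold in `[0, 1]`; sites strictly above are
#'   reported.
#' @param annotation_filter optional label; only sites whose panel
#'   annotation equals it are reported.
#' @return data.frame: `chrom`, `pos`, `fst`, `annotation`.
#' @export
high_fst_sites <- function(panel, pop_a, pop_b, samples, threshold = 0.5,
                           annotation_filter = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  cols_a <- which(samples$population == pop_a)
  cols_b <- which(samples$population == pop_b)
  comp <- wc_components_panel(panel, cols_a, cols_b)
  denom <- comp$a + comp$b + comp$c
  fst <- ifelse(!is.na(denom) & denom != 0, comp$a / denom, NA_real_)
  keep <- !is.na(fst) & fst > threshold
  if (!is.null(annotation_filter)) {
    ann <- panel$annotation
    if (is.null(ann)) stop("panel has no annotation")
    keep <- keep & !is.na(ann) & ann == annotation_filter
  }
  data.frame(chrom = panel$chrom[keep], pos = panel$pos[keep],
             fst = fst[keep],
             annotation = if (is.null(panel$annotation)) {
               rep(NA_character_, sum(keep))
             } else panel$annotation[keep])
}
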