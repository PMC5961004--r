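#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity: the probability that two chromosomes
#' drawn without replacement differ at the site,
#' `2 * k * (n - k) / (n * (n - 1))` for `k` alt alleles among `n`
#' chromosomes. Symmetric under allele relabeling.
#'
#' @param alt_count alt-allele count(s), `0 <= alt_count <= chrom_n`.
#' @param chrom_n number(s) of non-missing chromosomes; sites with
#'   `chrom_n < 2` return `NA` (skipped, not fatal).
#' @return numeric vector of per-site pi.
#' @export
site_pi <- function(alt_count, chrom_n) {
  out <- 2 * alt_count * (chrom_n - alt_count) / (chrom_n * (chrom_n - 1))
  out[chrom_n < 2] <- NA_real_
  out
}

# harmonic numbers a1 = sum 1/i and a2 = sum 1/i^2, i = 1..n-1
harmonic_a1 <- function(n) {
  vapply(n, function(k) if (k < 2) NA_real_ else sum(1 / seq_len(k - 1)),
         numeric(1))
}
harmonic_a2 <- function(n) {
  vapply(n, function(k) if (k < 2) NA_real_ else sum(1 / seq_len(k - 1)^2),
         numeric(1))
}

#' Watterson's theta
#'
#' `S / (a1 * span)` where `a1` is the harmonic number of the sample
#' size minus one; per-base when `span` is the surveyed length in bp.
#'
#' @param S segregating-site count (>= 0).
#' @param harmonic_sum `a1 = sum_{i=1}^{n-1} 1/i` for `n` chromosomes
#'   (see [harmonic_a1 via tajimas_d constants]); must be > 0.
#' @param span surveyed length in bp (> 0); use 1 for a per-locus value.
#' @return Watterson estimate.
#' @export
watterson_theta <- function(S, harmonic_sum, span = 1) {
  if (any(span <= 0)) stop("span must be > 0")
  if (any(harmonic_sum <= 0)) stop("harmonic_sum must be > 0")
  S / (harmonic_sum * span)
}

#' Tajima's D
#'
#' Normalized difference between the mean pairwise difference and the
#' Watterson expectation, with the standard (Tajima 1989) variance
#' constants. Negative values indicate an excess of rare alleles
#' (sweep or expansion), positive values an excess of intermediate
#' frequencies.
#'
#' @param S segregating-site count over the locus.
#' @param pi_sum unscaled sum of per-site pi over the locus (mean
#'   pairwise differences per sequence).
#' @param n number of chromosomes (>= 2).
#' @return D, or `NA` when `S == 0`. At `n == 2` the statistic is 0 for
#'   any `S > 0` (each segregating site contributes exactly one pairwise
#'   difference).
#' @export
tajimas_d <- function(S, pi_sum, n) {
  if (n < 2) stop("n must be >= 2")
  if (S == 0) return(NA_real_)
  if (n == 2) return(0)
  a1 <- harmonic_a1(n)
  a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Sliding-window diversity statistics for one population
#'
#' Per window: segregating sites `S`, per-base pi (sum of per-site pi
#' over the full window span), Watterson's theta (using the harmonic
#' number of the window-mean chromosome count) and Tajima's D. Missing
#' data are handled per site: each site uses its own non-missing
#' chromosome count; theta and D use the window-mean count rounded to
#' the nearest integer (>= 2). The denominator is the full window span
#' (uniform callability assumed) unless a callable-length per window is
#' supplied.
#'
#' @param panel a [genotype_panel()].
#' @param windows window data.frame from [make_windows()].
#' @param population population label to analyse.
#' @param samples sample sheet covering the panel columns.
#' @param callable optional numeric vector (one per window) of callable
#'   bp to use as the denominator instead of the window span.
#' @return data.frame: `chrom`, `start`, `end`, `index`, `population`,
#'   `n_sites_used`, `S`, `pi`, `theta_w`, `tajima_d`, `mean_chrom_n`,
#'   `low_confidence` (density < 0.1 x modal window density).
#' @export
window_diversity <- function(panel, windows, population, samples,
                             callable = NULL) {
  cols <- which(samples$population == population)
  if (!length(cols)) stop("unknown population label: ", population)
  ac <- allele_counts(panel, cols)
  if (max(ac$chrom_n, 0) < 2) stop("fewer than 2 chromosomes in population")
  sp <- site_pi(ac$alt_count, ac$chrom_n)
  usable <- ac$chrom_n >= 2
  poly <- usable & ac$alt_count > 0 & ac$alt_count < ac$chrom_n

  span <- windows$end - windows$start
  denom <- if (is.null(callable)) span else callable
  idx <- window_site_index(panel, windows)
  stats <- t(vapply(idx, function(i) {
    i <- i[usable[i]]
    if (!length(i)) return(c(n = 0, S = 0, pi_sum = 0, mean_n = NA_real_))
    c(n = length(i), S = sum(poly[i]), pi_sum = sum(sp[i]),
      mean_n = mean(ac$chrom_n[i]))
  }, numeric(4)))

  n_used <- stats[, "n"]
  S <- stats[, "S"]
  pi_sum <- stats[, "pi_sum"]
  mean_n <- stats[, "mean_n"]
  nbar <- pmax(2L, as.integer(round(mean_n)))
  a1 <- harmonic_a1(nbar)
  theta <- ifelse(n_used > 0, S / (a1 * denom), 0)
  D <- rep(NA_real_, nrow(windows))
  for (w in which(S > 0 & !is.na(mean_n) & mean_n >= 3)) {
    D[w] <- tajimas_d(S[w], pi_sum[w], nbar[w])
  }
  density <- n_used / span
  modal <- stats::median(density[n_used > 0])
  low <- n_used > 0 & density < 0.1 * modal

  data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    index = windows$index, population = population,
    n_sites_used = as.integer(n_used), S = as.integer(S),
    pi = pi_sum / denom, theta_w = theta, tajima_d = D,
    mean_chrom_n = mean_n, low_confidence = low
  )
}

# site indices per window; sites are 1-based positions, windows 0-based
# half-open, so site pos p lies in [start, end) iff start < p <= end;
# binary search per contig since pos is strictly increasing within chrom
window_site_index <- function(panel, windows) {
  out <- vector("list", nrow(windows))
  for (ctg in unique(windows$chrom)) {
    rows <- which(panel$chrom == ctg)
    p <- panel$pos[rows]
    wi <- which(windows$chrom == ctg)
    lo <- findInterval(windows$start[wi], p) + 1L
    hi <- findInterval(windows$end[wi], p)
    for (k in seq_along(wi)) {
      out[[wi[k]]] <- if (lo[k] <= hi[k]) rows[lo[k]:hi[k]] else integer(0)
    }
  }
  out
}
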