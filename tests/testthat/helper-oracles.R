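# Independent direct-transcription oracles. Each recomputes a statistic
# from first principles (enumeration or a literal one-to-one rendering of
# the published estimator), sharing no code with the package internals.

# mean pairwise difference per site from an explicit chromosome list
oracle_pi_site <- function(alt_count, chrom_n) {
  alleles <- c(rep(1, alt_count), rep(0, chrom_n - alt_count))
  if (chrom_n < 2) return(NA_real_)
  diffs <- 0; n_pairs <- 0
  for (i in 1:(chrom_n - 1)) {
    for (j in (i + 1):chrom_n) {
      diffs <- diffs + as.integer(alleles[i] != alleles[j])
      n_pairs <- n_pairs + 1
    }
  }
  diffs / n_pairs
}

# Tajima (1989) constants evaluated one by one
oracle_tajimas_d <- function(S, pi_sum, n) {
  if (S == 0) return(NA_real_)
  a1 <- 0; for (i in 1:(n - 1)) a1 <- a1 + 1 / i
  a2 <- 0; for (i in 1:(n - 1)) a2 <- a2 + 1 / i^2
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) eqs (2)-(4), literal transcription for r pops:
# n_i individuals, p_i alt frequency, h_i het proportion per population
oracle_wc <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# r^2 from explicit covariance and variances
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  sxx <- sum((x - mx)^2) / (n - 1)
  syy <- sum((y - my)^2) / (n - 1)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy^2 / (sxx * syy)
}

# IBS as an explicit per-pair, per-site loop over shared calls
oracle_ibs_pair <- function(gi, gj) {
  tot <- 0; nn <- 0
  for (s in seq_along(gi)) {
    if (!is.na(gi[s]) && !is.na(gj[s])) {
      tot <- tot + (2 - abs(gi[s] - gj[s])) / 2
      nn <- nn + 1
    }
  }
  if (nn == 0) NA_real_ else tot / nn
}

# method-of-moments F for one sample, literal estimator transcription
oracle_inbreeding_f <- function(g_dip, sample_col) {
  o_hom <- 0; e_hom <- 0; L <- 0
  for (s in seq_len(nrow(g_dip))) {
    gs <- g_dip[s, ]
    if (is.na(gs[sample_col])) next
    alt <- sum(gs, na.rm = TRUE)
    n <- 2 * sum(!is.na(gs))
    if (n < 2 || alt == 0 || alt == n) next
    p <- alt / n
    L <- L + 1
    e_hom <- e_hom + 1 - 2 * p * (1 - p) * n / (n - 1)
    o_hom <- o_hom + as.integer(gs[sample_col] != 1)
  }
  if (L == 0) return(NA_real_)
  (o_hom - e_hom) / (L - e_hom)
}

# centered kinship as an explicit per-site outer-product sum
oracle_kinship <- function(g_dip) {
  n <- ncol(g_dip)
  K <- matrix(0, n, n)
  for (s in seq_len(nrow(g_dip))) {
    x <- g_dip[s, ]
    mu <- mean(x, na.rm = TRUE)
    x <- x - mu
    x[is.na(x)] <- 0
    K <- K + outer(x, x)
  }
  K / nrow(g_dip)
}

# HWE exact: brute-force probability of every heterozygote configuration
# via multinomial coefficients (no recurrence, no log-space shortcut)
oracle_hwe_exact <- function(n_het, n_hom_alt, n_hom_ref) {
  n <- n_het + n_hom_alt + n_hom_ref
  n_a <- 2 * n_hom_alt + n_het   # alt alleles
  n_b <- 2 * n - n_a
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  prob <- sapply(hets, function(h) {
    na2 <- (n_a - h) / 2   # alt homozygotes
    nb2 <- (n_b - h) / 2
    exp(lgamma(n + 1) - lgamma(na2 + 1) - lgamma(h + 1) - lgamma(nb2 + 1) +
          h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1))
  })
  prob <- prob / sum(prob)
  p_obs <- prob[hets == n_het]
  sum(prob[prob <= p_obs + 1e-12])
}

# interval union by sweeping unit steps on a coarse grid
oracle_interval_union <- function(starts, ends, grid = 1) {
  if (!length(starts)) return(data.frame(start = numeric(), end = numeric()))
  lo <- min(starts); hi <- max(ends)
  covered <- rep(FALSE, (hi - lo) / grid)
  for (k in seq_along(starts)) {
    idx <- seq((starts[k] - lo) / grid + 1, (ends[k] - lo) / grid)
    covered[idx] <- TRUE
  }
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- c(1, head(stops, -1) + 1)
  keep <- r$values
  data.frame(start = lo + (begins[keep] - 1) * grid,
             end = lo + stops[keep] * grid)
}

# brute-force pairwise interval overlaps
oracle_interval_overlap <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (e > s) out[[length(out) + 1]] <- data.frame(chrom = a$chrom[i],
                                                    start = s, end = e)
  }
  if (!length(out)) return(data.frame(chrom = character(),
                                      start = numeric(), end = numeric()))
  do.call(rbind, out)
}

# Cochran-Armitage trend chi-square from the 2x3 table, textbook form
oracle_trend_chi2 <- function(d, y, scores = NULL) {
  lev <- sort(unique(d))
  if (is.null(scores)) scores <- lev
  n_k <- sapply(lev, function(l) sum(d == l))
  r_k <- sapply(lev, function(l) sum(d == l & y))
  N <- sum(n_k); R <- sum(r_k)
  num <- (sum(scores * r_k) - R / N * sum(scores * n_k))^2
  den <- R / N * (1 - R / N) *
    (sum(scores^2 * n_k) - sum(scores * n_k)^2 / N)
  num / den
}
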