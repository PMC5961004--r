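#' Squared genotype correlation between two sites
#'
#' Composite (genotype-dosage) r2: the squared Pearson correlation of
#' dosage vectors over jointly non-missing samples. Needs no phase and
#' is invariant under allele-label flips of either site.
#'
#' @param dosages_i,dosages_j numeric dosage vectors over the same
#'   samples (`NA` = missing).
#' @return r2 in `[0, 1]`, or `NA` if fewer than 2 jointly non-missing
#'   samples or either site is monomorphic in that subset.
#' @export
r2_pair <- function(dosages_i, dosages_j) {
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosages_i[ok]; y <- dosages_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD decay curve
#'
#' Mean r2 of all intra-contig site pairs, binned by physical
#' separation. The half-decay distance is where the curve first drops
#' to half its maximum bin mean, linearly interpolated between adjacent
#' occupied bin midpoints (`NA` if the curve never drops that far;
#' the first bin midpoint if it starts below half-maximum).
#'
#' @param panel a [genotype_panel()].
#' @param population population label, or `NULL` for all samples.
#' @param samples sample sheet (required when `population` is given).
#' @param max_dist maximum pair separation in bp (default 300 kb).
#' @param bin_width bin width in bp; `0 < bin_width < max_dist`.
#' @param thin_to maximum sites used per contig (default 2000): a
#'   dense panel is thinned to every k-th site, which preserves the
#'   distance structure of the curve while keeping the pair count
#'   tractable; `Inf` disables thinning.
#' @return list of class `ld_decay`: data.frame `bins` (`bin_start`,
#'   `bin_end`, `mid`, `mean_r2`, `n_pairs`) and `half_decay_distance`.
#' @export
ld_decay <- function(panel, population = NULL, samples = NULL,
                     max_dist = 3e5, bin_width = 1e3, thin_to = 2000L) {
  if (bin_width <= 0 || bin_width >= max_dist) {
    stop("require 0 < bin_width < max_dist")
  }
  cols <- ld_sample_cols(panel, population, samples)
  g <- panel$geno[, cols, drop = FALSE]
  if (nrow(g) < 2) stop("fewer than 2 usable sites")
  n_bins <- ceiling(max_dist / bin_width)
  sum_r2 <- numeric(n_bins); n_pairs <- integer(n_bins)
  for (ctg in unique(panel$chrom)) {
    rows <- which(panel$chrom == ctg)
    if (length(rows) > thin_to) {
      rows <- rows[seq(1L, length(rows),
                       by = ceiling(length(rows) / thin_to))]
    }
    p <- panel$pos[rows]
    for (ii in seq_along(rows)) {
      jj <- ii + 1L
      while (jj <= length(rows) && p[jj] - p[ii] <= max_dist) {
        r2 <- r2_pair(g[rows[ii], ], g[rows[jj], ])
        if (!is.na(r2)) {
          b <- ceiling((p[jj] - p[ii]) / bin_width)
          sum_r2[b] <- sum_r2[b] + r2
          n_pairs[b] <- n_pairs[b] + 1L
        }
        jj <- jj + 1L
      }
    }
  }
  bins <- data.frame(
    bin_start = (seq_len(n_bins) - 1) * bin_width,
    bin_end = pmin(seq_len(n_bins) * bin_width, max_dist),
    mid = (seq_len(n_bins) - 0.5) * bin_width,
    mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1L), NA_real_),
    n_pairs = n_pairs)
  structure(list(bins = bins,
                 half_decay_distance = half_decay_distance(bins)),
            class = "ld_decay")
}

ld_sample_cols <- function(panel, population, samples) {
  if (is.null(population)) return(seq_len(n_samples(panel)))
  if (is.null(samples)) stop("samples sheet required with a population label")
  cols <- which(samples$population == population)
  if (!length(cols)) stop("unknown population label: ", population)
  cols
}

half_decay_distance <- function(bins) {
  occ <- bins[!is.na(bins$mean_r2), , drop = FALSE]
  if (nrow(occ) == 0) return(NA_real_)
  target <- max(occ$mean_r2) / 2
  if (occ$mean_r2[1] <= target) return(occ$mid[1])
  below <- which(occ$mean_r2 <= target)
  if (!length(below)) return(NA_real_)
  k <- below[1]
  x0 <- occ$mid[k - 1]; y0 <- occ$mean_r2[k - 1]
  x1 <- occ$mid[k]; y1 <- occ$mean_r2[k]
  x0 + (y0 - target) / (y0 - y1) * (x1 - x0)
}

#' Greedy sliding-window LD pruning
#'
#' PLINK-style `indep-pairwise` pass over each contig: within windows
#' of `window_n` currently-kept sites advancing by `step_n`, while any
#' pair has r2 above `r2_max`, the member of the worst pair with higher
#' missingness (ties: larger position) is removed. A banded
#' verification sweep then removes any residual pair closer than
#' `window_n` kept sites, so the output contains no violating pair in
#' any window of `window_n` consecutive kept sites.
#'
#' @param panel a [genotype_panel()].
#' @param window_n sites per window (default 50).
#' @param step_n window advance in sites (default 10); `< window_n`.
#' @param r2_max removal threshold (default 0.2).
#' @return integer vector of kept site indices (into the panel).
#' @export
ld_prune <- function(panel, window_n = 50L, step_n = 10L, r2_max = 0.2) {
  if (!(window_n > step_n && step_n > 0)) stop("require window_n > step_n > 0")
  g <- panel$geno
  miss <- rowSums(is.na(g))
  drop_of <- function(pair) {
    if (miss[pair[1]] != miss[pair[2]]) pair[which.max(miss[pair])]
    else pair[which.max(panel$pos[pair])]
  }
  kept <- rep(TRUE, n_sites(panel))
  for (ctg in unique(panel$chrom)) {
    rows <- which(panel$chrom == ctg)
    # bulk PLINK-style windowed passes
    repeat {
      removed_any <- FALSE
      cur <- rows[kept[rows]]
      if (length(cur) < 2) break
      for (s in seq(1L, length(cur), by = step_n)) {
        w <- cur[s:min(s + window_n - 1L, length(cur))]
        w <- w[kept[w]]
        while (length(w) >= 2) {
          r2 <- suppressWarnings(
            stats::cor(t(g[w, , drop = FALSE]),
                       use = "pairwise.complete.obs")^2)
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          if (max(r2) <= r2_max) break
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          pair <- w[worst]
          kept[drop_of(pair)] <- FALSE
          removed_any <- TRUE
          w <- w[kept[w]]
        }
      }
      if (!removed_any) break
    }
    # banded verification: no kept pair within window_n indices may violate
    repeat {
      cur <- rows[kept[rows]]
      viol <- banded_violations(g, cur, window_n, r2_max)
      if (!nrow(viol)) break
      for (k in seq_len(nrow(viol))) {
        pair <- c(viol$i[k], viol$j[k])
        if (all(kept[pair])) kept[drop_of(pair)] <- FALSE
      }
    }
  }
  which(kept)
}

# pairs of sites (indices into g) violating r2_max among `cur` sites
# closer than window_n in kept-index distance, found block-wise
banded_violations <- function(g, cur, window_n, r2_max) {
  out <- list()
  n <- length(cur)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  block <- 400L
  starts <- seq(1L, n, by = block - window_n + 1L)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    if (e - s < 1L) next
    idx <- cur[s:e]
    r2 <- suppressWarnings(
      stats::cor(t(g[idx, , drop = FALSE]),
                 use = "pairwise.complete.obs")^2)
    r2[!is.finite(r2)] <- 0
    hit <- which(r2 > r2_max, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2] &
                 hit[, 2] - hit[, 1] < window_n, , drop = FALSE]
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- data.frame(i = idx[hit[, 1]],
                                            j = idx[hit[, 2]])
    }
    if (e == n) break
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  unique(do.call(rbind, out))
}
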