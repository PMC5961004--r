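#' Sweep-scan configuration
#'
#' Joint criteria for calling selective sweeps from windowed statistics:
#' ROD in the upper tail of its genome-wide distribution, strongly
#' negative Tajima's D in the domesticated population, and elevated
#' FST; qualifying windows are merged and short regions discarded.
#'
#' @param window_size,step scan geometry in bp (defaults 100 kb / 10 kb,
#'   the 90%-overlap scan).
#' @param rod_tail upper-tail mass for the ROD criterion (default 0.01:
#'   the 1% tail); must lie in (0, 0.5).
#' @param d_threshold fixed Tajima's D cutoff (default -2); used when
#'   `d_tail` is `NULL`.
#' @param d_tail optional lower-tail mass for a quantile-based D
#'   criterion instead of the fixed threshold.
#' @param fst_threshold FST cutoff (default 0.3); negative window FST is
#'   treated as 0 before comparison.
#' @param min_span merged regions must span strictly more than this
#'   (default 100 kb; must be >= `window_size`).
#' @return list of class `sweep_scan_config`.
#' @export
sweep_scan_config <- function(window_size = 1e5, step = 1e4,
                              rod_tail = 0.01, d_threshold = -2,
                              d_tail = NULL, fst_threshold = 0.3,
                              min_span = 1e5) {
  if (rod_tail <= 0 || rod_tail >= 0.5) stop("rod_tail must be in (0, 0.5)")
  if (min_span < window_size) stop("min_span must be >= window_size")
  structure(list(window_size = window_size, step = step,
                 rod_tail = rod_tail, d_threshold = d_threshold,
                 d_tail = d_tail, fst_threshold = fst_threshold,
                 min_span = min_span),
            class = "sweep_scan_config")
}

#' Classify windows by the joint sweep criteria
#'
#' A window qualifies iff its ROD reaches the empirical upper
#' `rod_tail` quantile of all non-missing ROD values (linear
#' interpolation, genome-wide per comparison), the domesticated
#' population's Tajima's D is below the threshold, and FST (negative
#' values floored at 0) exceeds its threshold. Windows with any missing
#' statistic never qualify.
#'
#' @param div_dom [window_diversity()] table for the domesticated
#'   population.
#' @param fst [window_fst()] table.
#' @param rod [window_rod()] table.
#' @param cfg a [sweep_scan_config()].
#' @return logical vector, one flag per window.
#' @export
classify_windows <- function(div_dom, fst, rod, cfg = sweep_scan_config()) {
  if (!identical(div_dom$index, fst$index) ||
      !identical(div_dom$index, rod$index)) {
    stop("window lists are misaligned")
  }
  rod_v <- rod$rod
  d_v <- div_dom$tajima_d
  fst_v <- pmax(fst$fst, 0)
  if (!any(!is.na(rod_v))) return(rep(FALSE, length(rod_v)))
  rod_cut <- stats::quantile(rod_v, probs = 1 - cfg$rod_tail, na.rm = TRUE,
                             names = FALSE, type = 7)
  d_cut <- if (is.null(cfg$d_tail)) cfg$d_threshold
           else stats::quantile(d_v, probs = cfg$d_tail, na.rm = TRUE,
                                names = FALSE, type = 7)
  flag <- !is.na(rod_v) & !is.na(d_v) & !is.na(fst_v) &
    rod_v >= rod_cut & d_v < d_cut & fst_v > cfg$fst_threshold
  flag
}

#' Merge flagged windows into sweep regions
#'
#' Overlapping or abutting qualifying windows are unioned into maximal
#' intervals; regions whose span is not strictly greater than
#' `min_span` are discarded. Region statistics are extrema over member
#' windows.
#'
#' @param flags logical vector aligned to `windows`.
#' @param windows window data.frame.
#' @param cfg a [sweep_scan_config()].
#' @param rod,div_dom,fst optional aligned statistic tables used to fill
#'   the supporting extrema (`max_rod`, `min_d`, `max_fst`).
#' @return data.frame: `chrom`, `start`, `end`, `n_windows`, `max_rod`,
#'   `min_d`, `max_fst`.
#' @export
merge_regions <- function(flags, windows, cfg = sweep_scan_config(),
                          rod = NULL, div_dom = NULL, fst = NULL) {
  if (length(flags) != nrow(windows)) stop("flags misaligned to windows")
  out <- list()
  for (ctg in unique(windows$chrom)) {
    wi <- which(windows$chrom == ctg & flags)
    if (!length(wi)) next
    wi <- wi[order(windows$start[wi])]
    starts <- windows$start[wi]; ends <- windows$end[wi]
    grp <- cumsum(c(1, as.integer(starts[-1] > cummax(ends[-length(ends)]))))
    for (g in unique(grp)) {
      m <- wi[grp == g]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ctg, start = min(windows$start[m]),
        end = max(windows$end[m]), n_windows = length(m),
        max_rod = if (is.null(rod)) NA_real_ else max(rod$rod[m], na.rm = TRUE),
        min_d = if (is.null(div_dom)) NA_real_
                else min(div_dom$tajima_d[m], na.rm = TRUE),
        max_fst = if (is.null(fst)) NA_real_ else max(fst$fst[m], na.rm = TRUE))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      max_rod = numeric(), min_d = numeric(),
                      max_fst = numeric()))
  }
  reg <- do.call(rbind, out)
  reg <- reg[reg$end - reg$start > cfg$min_span, , drop = FALSE]
  reg <- reg[order(reg$chrom, reg$start), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Intersect two sweep-region sets
#'
#' Pairwise positive-length interval intersections between two region
#' tables in the same coordinate space (e.g. egg-vs-wild and
#' meat-vs-wild sweeps), annotated with the source intervals.
#'
#' @param regions_a,regions_b region data.frames with `chrom`, `start`,
#'   `end`.
#' @return data.frame: `chrom`, `start`, `end`, `a_start`, `a_end`,
#'   `b_start`, `b_end`.
#' @export
intersect_sweeps <- function(regions_a, regions_b) {
  out <- list()
  for (i in seq_len(nrow(regions_a))) {
    on_ctg <- which(regions_b$chrom == regions_a$chrom[i])
    for (j in on_ctg) {
      s <- max(regions_a$start[i], regions_b$start[j])
      e <- min(regions_a$end[i], regions_b$end[j])
      if (e > s) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = regions_a$chrom[i], start = s, end = e,
          a_start = regions_a$start[i], a_end = regions_a$end[i],
          b_start = regions_b$start[j], b_end = regions_b$end[j])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), a_start = numeric(),
                      a_end = numeric(), b_start = numeric(),
                      b_end = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full sweep scan for one domesticated-vs-wild comparison
#'
#' Convenience wrapper: window diversity in both populations, FST, ROD,
#' classification and merging in one call.
#'
#' @param panel a [genotype_panel()].
#' @param samples sample sheet.
#' @param dom,wild population labels.
#' @param contig_lengths named contig-length vector for windowing.
#' @param cfg a [sweep_scan_config()].
#' @return list with `windows`, `div_dom`, `div_wild`, `fst`, `rod`,
#'   `flags`, `regions`.
#' @export
sweep_scan <- function(panel, samples, dom, wild, contig_lengths,
                       cfg = sweep_scan_config()) {
  win <- make_windows(contig_lengths, cfg$window_size, cfg$step)
  div_dom <- window_diversity(panel, win, dom, samples)
  div_wild <- window_diversity(panel, win, wild, samples)
  fst <- window_fst(panel, win, dom, wild, samples)
  rodt <- window_rod(div_dom, div_wild)
  flags <- classify_windows(div_dom, fst, rodt, cfg)
  regions <- merge_regions(flags, win, cfg, rod = rodt, div_dom = div_dom,
                           fst = fst)
  list(windows = win, div_dom = div_dom, div_wild = div_wild, fst = fst,
       rod = rodt, flags = flags, regions = regions)
}
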