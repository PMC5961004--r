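#' Exact test for Hardy-Weinberg equilibrium
#'
#' Full enumeration of heterozygote counts conditional on the observed
#' allele counts (the exact test of Wigginton et al.); the P-value is
#' the summed probability of all configurations no more probable than
#' the observed one.
#'
#' @param n_het heterozygote count.
#' @param n_hom_alt,n_hom_ref homozygote counts.
#' @return exact two-sided P-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_alt, n_hom_ref) {
  n <- n_het + n_hom_alt + n_hom_ref
  if (n == 0) return(NA_real_)
  rare <- 2 * min(n_hom_alt, n_hom_ref) + n_het
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- lfactorial(n) - lfactorial((rare - hets) / 2) -
    lfactorial(hets) - lfactorial(n - (rare + hets) / 2) +
    hets * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
    lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# diploid-code a genotype matrix: hemizygous dosage d observed as 2d hom
diploid_coded <- function(panel) {
  g <- panel$geno
  g[panel$ploidy == 1L] <- 2L * g[panel$ploidy == 1L]
  g
}

#' Method-of-moments inbreeding coefficient F
#'
#' Excess-homozygosity F over the given sites, treating every call as
#' diploid-coded (a hemizygous call is observed as a homozygote, which
#' is what makes F a sex check on the Z chromosome of a ZW system):
#' `F = (O_hom - E_hom) / (L - E_hom)` with
#' `E_hom = sum(1 - 2*p*q*n/(n-1))` over used sites, allele frequencies
#' estimated from the whole panel.
#'
#' @param panel a [genotype_panel()] (restrict to the Z contig for sex
#'   checking; see [sex_check()]).
#' @param sample column index or sample id.
#' @return F, or `NA` with no usable site.
#' @export
inbreeding_f <- function(panel, sample) {
  if (is.character(sample)) sample <- match(sample, colnames(panel$geno))
  g <- diploid_coded(panel)
  obs <- !is.na(g)
  alt <- rowSums(g * obs, na.rm = TRUE)
  cn <- 2 * rowSums(obs)
  use <- alt > 0 & alt < cn & cn >= 2 & !is.na(g[, sample])
  if (!any(use)) return(NA_real_)
  p <- alt[use] / cn[use]
  n <- cn[use]
  e_hom <- sum(1 - 2 * p * (1 - p) * n / (n - 1))
  o_hom <- sum(g[use, sample] != 1L)
  L <- sum(use)
  if (abs(L - e_hom) < .Machine$double.eps^0.5) return(NA_real_)
  (o_hom - e_hom) / (L - e_hom)
}

#' Sex check from Z-chromosome heterozygosity
#'
#' In a ZW system the female is hemizygous on Z: diploid-coded her Z
#' calls are all homozygous (F near 1), while the diploid ZZ male shows
#' ordinary heterozygosity (F near 0). A declared female is flagged
#' discordant when F < 0.8 and a declared male when F > 0.2; samples of
#' unknown sex are never flagged (noted indeterminate when F falls in
#' the 0.2-0.8 band). Run this before hemizygous collapsing (e.g. on a
#' panel read with `z_contig = NA`, or on a simulator panel whose
#' ploidy mask reflects the true sex): collapsing by the declared label
#' destroys the heterozygosity evidence.
#'
#' @param panel a [genotype_panel()] containing the Z contig.
#' @param samples sample sheet.
#' @param z_contig Z contig id (default `"chrZ"`).
#' @param f_female lower F bound for a declared female (default 0.8).
#' @param f_male upper F bound for a declared male (default 0.2).
#' @return data.frame: `sample_id`, `sex`, `f`, `flag`, `note`.
#' @export
sex_check <- function(panel, samples, z_contig = "chrZ",
                      f_female = 0.8, f_male = 0.2) {
  z_rows <- which(panel$chrom == z_contig)
  if (!length(z_rows)) stop("no sites on contig ", z_contig)
  pz <- subset_panel(panel, sites = z_rows)
  f <- vapply(seq_len(n_samples(pz)), function(j) inbreeding_f(pz, j),
              numeric(1))
  flag <- rep(FALSE, nrow(samples))
  note <- rep("", nrow(samples))
  is_f <- samples$sex == "female"
  is_m <- samples$sex == "male"
  flag[is_f] <- !is.na(f[is_f]) & f[is_f] < f_female
  flag[is_m] <- !is.na(f[is_m]) & f[is_m] > f_male
  unk <- !is_f & !is_m
  note[unk & !is.na(f) & f > f_male & f < f_female] <- "indeterminate"
  note[flag] <- "sex_discordant"
  data.frame(sample_id = samples$sample_id, sex = samples$sex, f = f,
             flag = flag, note = note, stringsAsFactors = FALSE)
}

#' SNP-level quality control
#'
#' Sites are removed in the stated order, each with one primary reason:
#' missing genotype rate (MGR) above `mgr_max`; significantly different
#' missingness between cases and controls; minor allele frequency below
#' `maf_min`; exact Hardy-Weinberg P below `hwe_p_min` (assessed in
#' controls when phenotype labels exist, whole cohort otherwise, and
#' only over diploid calls, since hemizygous sites violate HWE
#' assumptions by construction).
#'
#' @param panel a [genotype_panel()].
#' @param samples sample sheet.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param mgr_max maximum per-site missing rate (default 0.05).
#' @param hwe_p_min minimum HWE exact P (default 1e-4).
#' @param dm_p_max differential-missingness P cutoff (default 0.05).
#' @param dm_method `"chisq"` (two-proportion chi-square, default) or
#'   `"ttest"` (Welch t on the binary missingness indicator).
#' @return list: `panel` (filtered), `report` (a `qc_report`:
#'   `removed_sites` data.frame with `chrom`, `pos`, `reason`; counts
#'   per reason; echoed thresholds).
#' @export
snp_qc <- function(panel, samples, maf_min = 0.05, mgr_max = 0.05,
                   hwe_p_min = 1e-4, dm_p_max = 0.05,
                   dm_method = c("chisq", "ttest")) {
  dm_method <- match.arg(dm_method)
  g <- panel$geno
  n <- ncol(g)
  miss <- is.na(g)
  reason <- rep(NA_character_, n_sites(panel))

  mgr <- rowMeans(miss)
  reason[mgr > mgr_max] <- "missingness"

  is_case <- samples$phenotype == "case"
  is_ctrl <- samples$phenotype == "control"
  if (any(is_case) && any(is_ctrl)) {
    todo <- which(is.na(reason))
    p_dm <- differential_missingness_p(miss[todo, , drop = FALSE],
                                       is_case, is_ctrl, dm_method)
    reason[todo[!is.na(p_dm) & p_dm < dm_p_max]] <- "differential_missingness"
  }

  ac <- allele_counts(panel)
  maf <- pmin(ac$alt_count, ac$chrom_n - ac$alt_count) /
    pmax(ac$chrom_n, 1L)
  todo <- which(is.na(reason))
  reason[todo[maf[todo] < maf_min]] <- "maf"

  hwe_cols <- if (any(is_ctrl)) which(is_ctrl) else seq_len(n)
  todo <- which(is.na(reason))
  for (i in todo) {
    dip <- hwe_cols[panel$ploidy[i, hwe_cols] == 2L & !miss[i, hwe_cols]]
    if (length(dip) < 2) next
    gd <- g[i, dip]
    p <- hwe_exact_test(sum(gd == 1L), sum(gd == 2L), sum(gd == 0L))
    if (!is.na(p) && p < hwe_p_min) reason[i] <- "hwe"
  }

  keep <- is.na(reason)
  if (!any(keep)) warning("all sites removed by SNP QC")
  removed <- data.frame(chrom = panel$chrom[!keep], pos = panel$pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  report <- structure(list(
    removed_sites = removed,
    n_in = n_sites(panel), n_out = sum(keep),
    counts = table(factor(reason[!keep], levels = c(
      "missingness", "differential_missingness", "maf", "hwe"))),
    thresholds = list(maf_min = maf_min, mgr_max = mgr_max,
                      hwe_p_min = hwe_p_min, dm_p_max = dm_p_max,
                      dm_method = dm_method)), class = "qc_report")
  list(panel = subset_panel(panel, sites = which(keep)), report = report)
}

differential_missingness_p <- function(miss, is_case, is_ctrl, method) {
  m1 <- rowSums(miss[, is_case, drop = FALSE])
  m2 <- rowSums(miss[, is_ctrl, drop = FALSE])
  n1 <- sum(is_case); n2 <- sum(is_ctrl)
  if (method == "chisq") {
    # two-proportion chi-square without continuity correction
    p_pool <- (m1 + m2) / (n1 + n2)
    se2 <- p_pool * (1 - p_pool) * (1 / n1 + 1 / n2)
    z2 <- ifelse(se2 > 0, (m1 / n1 - m2 / n2)^2 / se2, 0)
    stats::pchisq(z2, df = 1, lower.tail = FALSE)
  } else {
    vapply(seq_along(m1), function(i) {
      x <- c(rep(1, m1[i]), rep(0, n1 - m1[i]))
      y <- c(rep(1, m2[i]), rep(0, n2 - m2[i]))
      if (stats::var(x) == 0 && stats::var(y) == 0) return(1)
      tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
    }, numeric(1))
  }
}

#' Pairwise identity-by-state matrix
#'
#' Mean over jointly non-missing sites of `(2 - |d_i - d_j|) / 2`;
#' diagonal 1; `NA` for pairs with no shared site.
#'
#' @param panel a [genotype_panel()].
#' @return symmetric samples x samples matrix.
#' @export
ibs_matrix <- function(panel) {
  g <- diploid_coded(panel)
  n <- ncol(g)
  if (n < 2) stop("need >= 2 samples")
  out <- diag(1, n)
  dimnames(out) <- list(colnames(g), colnames(g))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      out[i, j] <- out[j, i] <-
        if (!any(ok)) NA_real_
        else mean((2 - abs(g[ok, i] - g[ok, j])) / 2)
    }
  }
  out
}

#' Individual-level quality control
#'
#' Removes, in order and each with one primary reason: sex-discordant
#' samples ([sex_check()]); samples with a missing-call rate above
#' `ind_mgr_max`; then, for every remaining pair with IBS above
#' `ibs_max`, the member with the higher missing rate (ties: the
#' later column).
#'
#' @param panel a [genotype_panel()].
#' @param samples sample sheet.
#' @param ind_mgr_max maximum individual missing rate (default 0.10).
#' @param ibs_max maximum pairwise IBS (default 0.9).
#' @param ibs_maf_min minimum minor allele frequency of the sites used
#'   for the IBS step (default 0.05): on a rare-allele-heavy panel IBS
#'   between unrelated samples is dominated by shared reference
#'   homozygotes, so relatedness screening is done on common SNPs, as
#'   the standard toolchains do.
#' @param z_contig Z contig id for the sex check; `NA` skips it.
#' @return list: `panel`, `samples` (both filtered), `report` (a
#'   `qc_report` with `removed_individuals`).
#' @export
individual_qc <- function(panel, samples, ind_mgr_max = 0.10,
                          ibs_max = 0.9, ibs_maf_min = 0.05,
                          z_contig = "chrZ") {
  reason <- rep(NA_character_, nrow(samples))
  if (!is.na(z_contig) && any(panel$chrom == z_contig)) {
    sc <- sex_check(panel, samples, z_contig)
    reason[sc$flag] <- "sex_discordant"
  }
  mgr <- colMeans(is.na(panel$geno))
  reason[is.na(reason) & mgr > ind_mgr_max] <- "high_missing"

  alive <- which(is.na(reason))
  if (length(alive) >= 2) {
    ac <- allele_counts(panel)
    maf <- pmin(ac$alt_count, ac$chrom_n - ac$alt_count) /
      pmax(ac$chrom_n, 1L)
    common <- which(maf >= ibs_maf_min)
    if (!length(common)) common <- seq_len(n_sites(panel))
    ibs <- ibs_matrix(subset_panel(panel, sites = common,
                                   samples = alive))
    diag(ibs) <- NA
    repeat {
      if (all(is.na(ibs)) || max(ibs, na.rm = TRUE) <= ibs_max) break
      worst <- which(ibs == max(ibs, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      pair <- alive[worst]
      drop <- if (mgr[pair[1]] != mgr[pair[2]]) {
        pair[which.max(mgr[pair])]
      } else max(pair)
      reason[drop] <- "related"
      k <- which(alive == drop)
      ibs[k, ] <- NA; ibs[, k] <- NA
    }
  }

  keep <- is.na(reason)
  removed <- data.frame(sample_id = samples$sample_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  report <- structure(list(
    removed_individuals = removed,
    n_in = nrow(samples), n_out = sum(keep),
    thresholds = list(ind_mgr_max = ind_mgr_max, ibs_max = ibs_max)),
    class = "qc_report")
  list(panel = subset_panel(panel, samples = which(keep)),
       samples = samples[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_in, "->", x$n_out, "\n")
  if (!is.null(x$removed_sites) && nrow(x$removed_sites)) {
    print(table(x$removed_sites$reason))
  }
  if (!is.null(x$removed_individuals) && nrow(x$removed_individuals)) {
    print(x$removed_individuals)
  }
  invisible(x)
}

#' Centered relatedness (kinship) matrix
#'
#' `K = (1/m) * sum_sites` of the outer product of the mean-centered
#' dosage vector (missing calls imputed with the site mean), the
#' centered genomic relationship matrix used as the random-effect
#' covariance in mixed-model association. Symmetric and positive
#' semidefinite by construction.
#'
#' @param panel a [genotype_panel()] with at least one polymorphic site.
#' @return samples x samples matrix.
#' @export
kinship_centered <- function(panel) {
  if (n_samples(panel) < 2) stop("need >= 2 samples")
  g <- diploid_coded(panel)
  mu <- rowMeans(g, na.rm = TRUE)
  poly <- !is.na(mu) & mu > 0 & mu < 2
  if (!any(poly)) stop("no polymorphic site")
  x <- g - mu
  x[is.na(x)] <- 0
  crossprod(x) / n_sites(panel)
}
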