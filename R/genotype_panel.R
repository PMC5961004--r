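#' Construct a genotype panel
#'
#' A `genotype_panel` is the substrate of every analysis stage: a sites x
#' samples matrix of alt-allele dosages with per-site metadata and a
#' per-call ploidy mask. Positions are stored 1-based (as in VCF); all
#' window arithmetic elsewhere in the package is 0-based half-open.
#'
#' @param chrom character vector of contig ids, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each contig.
#' @param ref,alt single-character alleles per site; `ref != alt`.
#' @param geno integer matrix (sites x samples) of alt-allele dosage in
#'   `0:2`, `NA` for missing calls.
#' @param ploidy integer matrix (sites x samples) of call ploidy, 1 for
#'   hemizygous calls (e.g. female Z in a ZW system), 2 otherwise. A
#'   scalar 1 or 2 is recycled. Dosage must not exceed ploidy.
#' @param annotation optional character vector of per-site functional
#'   labels (`"synonymous"`, `"non-synonymous"`, `"other"`), `NA` for
#'   unannotated sites.
#' @param sample_ids character vector of column names; defaults to the
#'   column names of `geno`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `chrom`, `pos`, `ref`, `alt`, `geno`, `ploidy`, `annotation`.
#' @export
genotype_panel <- function(chrom, pos, ref, alt, geno, ploidy = 2L,
                           annotation = NULL, sample_ids = colnames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- nrow(geno)
  if (length(chrom) != n_sites || length(pos) != n_sites ||
      length(ref) != n_sites || length(alt) != n_sites) {
    stop("site metadata length does not match nrow(geno)")
  }
  if (length(ploidy) == 1L) {
    ploidy <- matrix(as.integer(ploidy), n_sites, ncol(geno))
  }
  ploidy <- as.matrix(ploidy)
  storage.mode(ploidy) <- "integer"
  if (!all(dim(ploidy) == dim(geno))) stop("ploidy dimensions must match geno")
  if (!all(ploidy %in% c(1L, 2L))) stop("ploidy must be 1 or 2")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(geno)))
  colnames(geno) <- colnames(ploidy) <- sample_ids

  bad <- !is.na(geno) & (geno < 0L | geno > ploidy)
  if (any(bad)) stop("dosage exceeds ploidy (or is negative) at ",
                     sum(bad), " call(s)")
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L) || any(ref == alt)) {
    stop("sites must be biallelic SNPs with single-base ref != alt")
  }
  pos <- as.integer(pos)
  for (ctg in unique(chrom)) {
    p <- pos[chrom == ctg]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on contig ", ctg)
    }
  }
  if (!is.null(annotation) && length(annotation) != n_sites) {
    stop("annotation length must match the number of sites")
  }
  structure(
    list(chrom = as.character(chrom), pos = pos,
         ref = as.character(ref), alt = as.character(alt),
         geno = geno, ploidy = ploidy,
         annotation = if (is.null(annotation)) NULL else as.character(annotation)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", n_sites(x), "sites x", n_samples(x), "samples\n")
  cat("  contigs:", paste(unique(x$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (!is.null(x$annotation)) {
    cat("  annotated sites:", sum(!is.na(x$annotation)), "\n")
  }
  invisible(x)
}

#' Panel dimensions
#' @param panel a [genotype_panel()].
#' @return integer count.
#' @export
n_sites <- function(panel) nrow(panel$geno)

#' @rdname n_sites
#' @export
n_samples <- function(panel) ncol(panel$geno)

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Subset a panel by sites and/or samples
#'
#' @param panel a [genotype_panel()].
#' @param sites integer or logical index over sites (rows).
#' @param samples integer, logical or character index over samples.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(panel))
  if (is.null(samples)) samples <- seq_len(n_samples(panel))
  genotype_panel(
    chrom = panel$chrom[sites], pos = panel$pos[sites],
    ref = panel$ref[sites], alt = panel$alt[sites],
    geno = panel$geno[sites, samples, drop = FALSE],
    ploidy = panel$ploidy[sites, samples, drop = FALSE],
    annotation = if (is.null(panel$annotation)) NULL else panel$annotation[sites]
  )
}

#' Per-population allele counts at every site
#'
#' Ploidy-aware alt-allele and chromosome counts over a subset of sample
#' columns, skipping missing calls.
#'
#' @param panel a [genotype_panel()].
#' @param samples index over sample columns (default: all).
#' @return data.frame with columns `alt_count`, `chrom_n` (non-missing
#'   chromosomes) per site.
#' @export
allele_counts <- function(panel, samples = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(panel))
  g <- panel$geno[, samples, drop = FALSE]
  pl <- panel$ploidy[, samples, drop = FALSE]
  obs <- !is.na(g)
  data.frame(
    alt_count = as.integer(rowSums(g * obs, na.rm = TRUE)),
    chrom_n = as.integer(rowSums(pl * obs))
  )
}

#' Read a sample sheet
#'
#' Headered TSV with columns `sample_id`, `population`, `sex`
#' (`male`/`female`/`unknown`) and `phenotype` (`case`/`control`/`missing`).
#'
#' @param path file path.
#' @return data.frame with the four columns, ids unique.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "population", "sex", "phenotype")
  if (!all(need %in% names(ss))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample ids in sample sheet")
  ss[, need]
}
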