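#' Read a multi-sample VCF into a genotype panel
#'
#' Restricts to biallelic SNP records (single-base REF and ALT); non-SNP
#' and multi-allelic records are dropped, and half-calls (e.g. `./1`) are
#' set to missing; both with a reported count. On the hemizygous sex
#' chromosome, calls for samples of the heterogametic sex are collapsed
#' to ploidy 1: a diploid-coded homozygote becomes dosage 0 or 1 and a
#' (biologically impossible) heterozygote becomes missing.
#'
#' @param path VCF 4.x file (plain or bgzipped) with GT fields.
#' @param sample_sheet path to a sample-sheet TSV (see
#'   [read_sample_sheet()]), or an already-read data.frame. Must cover
#'   every sample in the VCF.
#' @param z_contig contig id of the hemizygous sex chromosome
#'   (default `"chrZ"`); set `NA` to disable hemizygous handling.
#' @param heterogametic sex that is hemizygous on `z_contig`
#'   (default `"female"`, the ZW convention).
#' @param verbose print drop counts.
#' @return list with elements `panel` (a [genotype_panel()]) and
#'   `samples` (the sample sheet, ordered as the panel columns).
#' @export
read_vcf <- function(path, sample_sheet, z_contig = "chrZ",
                     heterogametic = "female", verbose = FALSE) {
  ss <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
        else sample_sheet
  need <- c("sample_id", "population", "sex", "phenotype")
  if (!all(need %in% names(ss))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) & ref != alt
  n_dropped <- sum(!is_snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[is_snp, , drop = FALSE]
  chrom <- fix[is_snp, "CHROM"]
  pos <- as.integer(fix[is_snp, "POS"])
  ref <- ref[is_snp]
  alt <- alt[is_snp]
  if (anyDuplicated(paste(chrom, pos))) stop("duplicate (chrom, pos) records in VCF")

  vcf_samples <- colnames(gt)
  missing_ss <- setdiff(vcf_samples, ss$sample_id)
  if (length(missing_ss)) {
    stop("samples in VCF absent from sample sheet: ",
         paste(missing_ss, collapse = ", "))
  }
  ss <- ss[match(vcf_samples, ss$sample_id), , drop = FALSE]
  rownames(ss) <- NULL

  # decode GT strings through a lookup over the few observed patterns
  pats <- unique(as.vector(gt))
  dose <- vapply(pats, function(p) {
    if (is.na(p)) return(NA_integer_)
    al <- strsplit(p, "[/|]")[[1]]
    if (any(al == ".") || any(is.na(al))) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  g <- matrix(dose[match(as.vector(gt), pats)], nrow = nrow(gt),
              dimnames = list(NULL, colnames(gt)))
  n_half <- sum(is.na(g) & !is.na(gt) & gt != "./." & gt != "." & gt != ".|.")

  ploidy <- matrix(2L, nrow(g), ncol(g))
  n_hemi_het <- 0L
  if (!is.na(z_contig) && any(chrom == z_contig)) {
    hemi_cols <- which(ss$sex == heterogametic)
    z_rows <- which(chrom == z_contig)
    if (length(hemi_cols) && length(z_rows)) {
      sub <- g[z_rows, hemi_cols, drop = FALSE]
      het <- !is.na(sub) & sub == 1L
      n_hemi_het <- sum(het)
      sub[het] <- NA_integer_
      sub <- sub %/% 2L  # diploid-coded hom -> haploid dosage
      g[z_rows, hemi_cols] <- sub
      ploidy[z_rows, hemi_cols] <- 1L
    }
  }
  if (verbose) {
    message(sprintf(
      "read_vcf: kept %d biallelic SNPs (%d records dropped, %d half-calls and %d hemizygous heterozygotes set missing)",
      length(pos), n_dropped, n_half, n_hemi_het))
  }
  panel <- genotype_panel(chrom, pos, ref, alt, g, ploidy,
                          sample_ids = vcf_samples)
  list(panel = panel, samples = ss,
       dropped = c(non_biallelic = n_dropped, half_calls = n_half,
                   hemizygous_het = n_hemi_het))
}

#' Write a genotype panel as a plain-text VCF
#'
#' All calls are written as unphased diploid GT fields, the way variant
#' callers emit them: a hemizygous (ploidy 1) dosage `d` is written as
#' the homozygote `d/d`-style call. [read_vcf()] with a `z_contig`
#' restores ploidy-1 dosages, making the round trip dosage-identical.
#'
#' @param panel a [genotype_panel()].
#' @param path output path (`.vcf`, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=popscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(panel$geno)), collapse = "\t")), con)
  if (n_sites(panel) == 0L) return(invisible(path))
  dip <- c("0/0", "0/1", "1/1")
  g <- panel$geno
  # diploid-code hemizygous calls: haploid dosage d -> homozygote 2d
  g[panel$ploidy == 1L] <- 2L * g[panel$ploidy == 1L]
  gt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gt[ok] <- dip[g[ok] + 1L]
  lines <- paste(panel$chrom, panel$pos, ".", panel$ref, panel$alt,
                 ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a sample sheet TSV
#' @param samples sample-sheet data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse hemizygous calls on the sex chromosome
#'
#' Marks calls of the heterogametic sex on the hemizygous contig as
#' ploidy 1: diploid-coded homozygotes become haploid dosage 0/1 and
#' (impossible) heterozygotes become missing. [read_vcf()] applies this
#' automatically; use it directly on in-memory panels.
#'
#' @param panel a [genotype_panel()].
#' @param samples sample sheet aligned to the panel columns.
#' @param z_contig hemizygous contig id (default `"chrZ"`).
#' @param heterogametic hemizygous sex label (default `"female"`).
#' @return the panel with ploidy mask and dosages updated.
#' @export
apply_hemizygosity <- function(panel, samples, z_contig = "chrZ",
                               heterogametic = "female") {
  hemi_cols <- which(samples$sex == heterogametic)
  z_rows <- which(panel$chrom == z_contig)
  if (length(hemi_cols) && length(z_rows)) {
    sub <- panel$geno[z_rows, hemi_cols, drop = FALSE]
    pl <- panel$ploidy[z_rows, hemi_cols, drop = FALSE]
    dip <- pl == 2L
    sub[dip & !is.na(sub) & sub == 1L] <- NA_integer_
    sub[dip] <- sub[dip] %/% 2L
    panel$geno[z_rows, hemi_cols] <- sub
    panel$ploidy[z_rows, hemi_cols] <- 1L
  }
  panel
}

#' Build sliding windows over contigs
#'
#' Windows are 0-based half-open `[start, end)`. Per contig, starts run
#' `0, step, 2*step, ...`; a window is emitted iff its start is inside
#' the contig and its end is clamped to the contig length. The default
#' 100-kb window with 10-kb step gives the 90%-overlap scan used
#' throughout the package.
#'
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param size window size in bp (> 0).
#' @param step step in bp, `0 < step <= size`.
#' @return data.frame with columns `chrom`, `start`, `end`, `index`
#'   (ordinal over the whole list).
#' @export
make_windows <- function(contig_lengths, size = 1e5, step = 1e4) {
  if (length(contig_lengths) == 0L) stop("empty contig map")
  if (is.null(names(contig_lengths)) || any(names(contig_lengths) == "")) {
    stop("contig_lengths must be named")
  }
  if (size <= 0) stop("size must be > 0")
  if (step <= 0 || step > size) stop("require 0 < step <= size")
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(0, len - 1, by = step)
    starts <- starts[starts < len]
    data.frame(chrom = ctg, start = starts,
               end = pmin(starts + size, len))
  })
  win <- do.call(rbind, out)
  win$index <- seq_len(nrow(win))
  rownames(win) <- NULL
  win
}

#' Summarise functional annotation of a panel
#'
#' Counts non-synonymous (N) and synonymous (S) sites and their ratio
#' N/S, the standard coarse readout of coding constraint in a SNP set.
#'
#' @param x a [genotype_panel()] with `annotation`, or a character vector
#'   of per-site labels (`"non-synonymous"`, `"synonymous"`, others
#'   ignored).
#' @return list with `n_nonsyn`, `n_syn`, `ns_ratio` (`NA` when S = 0).
#' @export
functional_site_summary <- function(x) {
  ann <- if (inherits(x, "genotype_panel")) x$annotation else as.character(x)
  if (is.null(ann) || !any(!is.na(ann))) stop("no annotated sites")
  n_n <- sum(ann == "non-synonymous", na.rm = TRUE)
  n_s <- sum(ann == "synonymous", na.rm = TRUE)
  list(n_nonsyn = n_n, n_syn = n_s,
       ns_ratio = if (n_s == 0L) NA_real_ else n_n / n_s)
}

#' Attach a per-site functional annotation table to a panel
#'
#' @param panel a [genotype_panel()].
#' @param annotation data.frame with columns `chrom`, `pos`, `label`, or
#'   a path to such a TSV.
#' @return the panel with its `annotation` field filled (`NA` where no
#'   table row matches).
#' @export
annotate_panel <- function(panel, annotation) {
  if (is.character(annotation)) {
    annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  }
  key_p <- paste(panel$chrom, panel$pos)
  key_a <- paste(annotation$chrom, annotation$pos)
  panel$annotation <- annotation$label[match(key_p, key_a)]
  panel
}
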