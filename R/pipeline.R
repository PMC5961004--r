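#' Run the full scan pipeline
#'
#' Chains the stages on a simulated panel (or a VCF input):
#' simulate/load -> individual and SNP QC -> per-population diversity
#' -> FST/ROD -> sweep scan -> LD decay/pruning -> association. Each
#' stage writes a table under `out_dir`; a manifest of outputs with
#' MD5 checksums is written last. All randomness derives from the root
#' seed through named substreams, so a rerun with the same config and
#' seed is bit-identical for every deterministic stage.
#'
#' @param config a run configuration: a YAML file path or a list with
#'   blocks `input` (either `vcf` + `samples` paths or a `sim` block of
#'   [sim_config()] fields), `scan` ([sweep_scan_config()] fields;
#'   `dom` and `wild` population labels), `qc`, `ld` (`max_dist`,
#'   `bin_width`), `assoc` (`n_perm`, and `enabled` which defaults to
#'   running only when phenotypes exist), `seed` and `out_dir`.
#' @param out_dir output directory, overriding the config.
#' @param seed root seed, overriding the config.
#' @return list with the stage results and `manifest` (data.frame of
#'   file, md5), invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("input", "scan", "qc", "ld", "assoc", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("out_dir required")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(...) message(sprintf(...))

  scan_cfg <- do.call(sweep_scan_config,
                      config$scan[setdiff(names(config$scan),
                                          c("dom", "wild"))] %||% list())
  dom <- config$scan$dom %||% "egg"
  wild <- config$scan$wild %||% "wild"

  # stage: input
  if (!is.null(config$input$vcf)) {
    logf("[input] reading %s", config$input$vcf)
    inp <- read_vcf(config$input$vcf, config$input$samples)
    panel <- inp$panel; samples <- inp$samples; truth <- NULL
    contig_lengths <- tapply(panel$pos, panel$chrom, max)
    contig_lengths <- stats::setNames(as.numeric(contig_lengths),
                                      names(contig_lengths))
  } else {
    sim_args <- config$input$sim %||% list()
    if (!is.null(sim_args$n_samples)) sim_args$n_samples <- unlist(sim_args$n_samples)
    if (!is.null(sim_args$contig_lengths)) sim_args$contig_lengths <- unlist(sim_args$contig_lengths)
    if (!is.null(sim_args$drift_F)) sim_args$drift_F <- unlist(sim_args$drift_F)
    scfg <- do.call(sim_config, sim_args)
    logf("[simulate] seed %d", substream_seed(seed, "simulate"))
    sim <- simulate_panel(scfg, seed = substream_seed(seed, "simulate"))
    panel <- sim$panel; samples <- sim$samples; truth <- sim$truth
    write_fixture(sim, file.path(out_dir, "fixture"))
    contig_lengths <- scfg$contig_lengths
  }

  # stage: qc
  qc_args <- config$qc %||% list()
  iqc <- do.call(individual_qc, c(list(panel = panel, samples = samples),
                                  qc_args[intersect(names(qc_args),
                                    c("ind_mgr_max", "ibs_max", "z_contig"))]))
  sqc <- do.call(snp_qc, c(list(panel = iqc$panel, samples = iqc$samples),
                           qc_args[intersect(names(qc_args),
                             c("maf_min", "mgr_max", "hwe_p_min",
                               "dm_p_max", "dm_method"))]))
  panel_qc <- sqc$panel; samples_qc <- iqc$samples
  logf("[qc] %d -> %d samples, %d -> %d sites",
       iqc$report$n_in, iqc$report$n_out, sqc$report$n_in, sqc$report$n_out)
  qc_path <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(list(
    individuals = iqc$report$removed_individuals,
    sites_removed = as.list(table(sqc$report$removed_sites$reason)),
    thresholds = c(iqc$report$thresholds, sqc$report$thresholds)),
    qc_path, auto_unbox = TRUE, digits = NA)

  # stage: diversity + fst + rod + sweep (note: diversity uses the
  # pre-SNP-QC panel -- MAF filters would bias the frequency spectrum)
  scan <- sweep_scan(iqc$panel, samples_qc, dom, wild, contig_lengths,
                     scan_cfg)
  logf("[sweep] %d qualifying windows, %d regions",
       sum(scan$flags), nrow(scan$regions))
  div_path <- file.path(out_dir, "diversity.tsv")
  utils::write.table(rbind(scan$div_dom, scan$div_wild), div_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fst_path <- file.path(out_dir, "fst.tsv")
  utils::write.table(cbind(scan$fst, rod = scan$rod$rod), fst_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed_path <- file.path(out_dir, "sweep_regions.bed")
  utils::write.table(scan$regions[, c("chrom", "start", "end")], bed_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  # stage: ld
  ld_args <- config$ld %||% list()
  ldc <- ld_decay(panel_qc, wild, samples_qc,
                  max_dist = ld_args$max_dist %||% 5e4,
                  bin_width = ld_args$bin_width %||% 1e3)
  ld_path <- file.path(out_dir, "ld_decay.tsv")
  utils::write.table(ldc$bins, ld_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kept <- ld_prune(panel_qc)
  prune_path <- file.path(out_dir, "ld_pruned_sites.tsv")
  utils::write.table(data.frame(chrom = panel_qc$chrom[kept],
                                pos = panel_qc$pos[kept]),
                     prune_path, sep = "\t", quote = FALSE, row.names = FALSE)
  logf("[ld] half-decay %.0f bp; pruning kept %d/%d sites",
       ldc$half_decay_distance %||% NA, length(kept), n_sites(panel_qc))

  # stage: association (only with case/control phenotypes)
  assoc_args <- config$assoc %||% list()
  has_cc <- any(samples_qc$phenotype == "case") &&
    any(samples_qc$phenotype == "control")
  enabled <- assoc_args$enabled %||% has_cc
  assoc_paths <- character(0)
  assoc_res <- NULL
  if (enabled) {
    assoc_res <- haplotype_association(
      panel_qc, samples_qc,
      n_perm = assoc_args$n_perm %||% 5000L,
      seed = substream_seed(seed, "assoc"))
    assoc_path <- file.path(out_dir, "assoc.tsv")
    utils::write.table(assoc_res$assoc, assoc_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hap_path <- file.path(out_dir, "haplotype_test.json")
    jsonlite::write_json(list(
      index_chrom = assoc_res$clump$chrom,
      index_pos = assoc_res$assoc$pos[assoc_res$clump$index_site],
      n_clumped = nrow(assoc_res$clump$members),
      chi2 = assoc_res$test$chi2, p_perm = assoc_res$test$p_perm,
      n_perm = assoc_res$test$n_perm),
      hap_path, auto_unbox = TRUE, digits = NA)
    assoc_paths <- c(assoc_path, hap_path)
    logf("[assoc] index %s:%d, chi2 = %.2f, perm P = %.3g",
         assoc_res$clump$chrom,
         assoc_res$assoc$pos[assoc_res$clump$index_site],
         assoc_res$test$chi2, assoc_res$test$p_perm)
  }

  files <- c(qc_path, div_path, fst_path, bed_path, ld_path, prune_path,
             assoc_paths)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(panel = panel_qc, samples = samples_qc, truth = truth,
                 scan = scan, ld = ldc, assoc = assoc_res,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
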