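Package: popscan
Title: Sliding-Window Selection Scans and Haplotype Association for
    Resequenced Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic selection scans for multi-population SNP
    panels in the style of domestication studies: per-window nucleotide
    diversity (pi), Watterson's theta and Tajima's D; Weir-Cockerham FST;
    the reduction-of-diversity (ROD) statistic; a composite selective-sweep
    caller with interval merging and cross-comparison intersection; the
    sample- and SNP-level quality-control cascade (Z-chromosome sex checks
    via the inbreeding F statistic, missingness, minor allele frequency,
    exact Hardy-Weinberg tests, identity-by-state relatedness); LD decay
    curves, PLINK-style LD pruning and a centered kinship matrix; and a
    conditional haplotype-based association stage (trend tests, Bonferroni
    adjustment, index-SNP clumping, Excoffier-Slatkin EM phasing and a
    permutation chi-squared haplotype test). A built-in frequency-first
    simulator generates three-population panels with planted sweeps,
    distance-decaying LD, a hemizygous Z chromosome and a haplotype-driven
    binary trait, with a truth ledger for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
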