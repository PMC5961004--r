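---
title: "Methods: selection scans and haplotype association in popscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and haplotype association in popscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popscan)
```

popscan detects footprints of recent directional (e.g. domestication)
selection by contrasting a "domesticated" population against a "wild"
reference in sliding windows, and localizes a binary trait to a
haplotype block by conditional haplotype association. This vignette
describes the statistical machinery, the choices made where the design
was genuinely open, and what the built-in simulator does and does not
emulate.

## Windowed diversity statistics

All window arithmetic is 0-based half-open; VCF input/output converts
to and from 1-based positions. The default scan uses 100-kb windows
advanced in 10-kb steps (90% overlap), so an interior site contributes
to exactly ten windows.

For a window of span $L$ and a population sample of $n_i$ non-missing
chromosomes at site $i$ (hemizygous Z calls count one chromosome,
diploid calls two):

* **Nucleotide diversity.** Per site,
  $\pi_i = 2 k_i (n_i - k_i) / (n_i (n_i - 1))$ with $k_i$ the
  alternate-allele count; the window value is $\sum_i \pi_i / L$. This
  is the unbiased probability that two chromosomes drawn without
  replacement differ.
* **Watterson's estimator.**
  $\theta_w = S / (a_1(\bar n)\, L)$, where $S$ counts sites
  polymorphic within the population and
  $a_1(n) = \sum_{j=1}^{n-1} 1/j$.
* **Tajima's D.** The 1989 statistic
  $D = (\sum_i \pi_i - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}$ with the
  standard constants $b_1, b_2, c_1, c_2, e_1, e_2$ evaluated at the
  window sample size.

**Missing data.** Each site uses its own non-missing chromosome count;
$\theta_w$ and $D$ use the window-mean count rounded to the nearest
integer ($\ge 2$), because the variance constants of $D$ have no
standard per-site form. $D$ is reported missing when $S = 0$ or the
mean chromosome count falls below 3 (at $n = 2$ the statistic is
identically 0 and carries no information).

**Denominator.** The full window span is used, which assumes uniform
callability; a per-window callable-length vector can replace it (the
`callable` argument), which is also the hook for restricting Table-1
style exon/intron summaries to feature length. Windows with fewer than
0.1x the median site density are flagged `low_confidence` but kept, to
avoid silently biasing scans across assembly gaps.

## Differentiation and the ROD statistic

Per-site Weir–Cockerham (1984) variance components $a$ (among
populations), $b$ (among individuals) and $c$ (within individuals) are
computed from allele frequencies and observed heterozygote
proportions. Hemizygous calls enter as half an individual with zero
heterozygosity, which reduces to the standard diploid formulation when
absent. The window estimator is the weighted ratio of sums
$\sum a / \sum (a + b + c)$ — the windowed default of the common VCF
toolchain — with a per-site-mean variant behind `method = "mean"`.
Negative estimates are reported as computed but floored at zero when
compared against the sweep threshold, since the scan's criteria are
one-sided.

The reduction of diversity is
$\mathrm{ROD} = 1 - \pi_\mathrm{dom} / \pi_\mathrm{wild}$ per window,
missing where $\pi_\mathrm{wild} = 0$: near 1 where domestication
erased variation, near 0 under equal diversity.

## The sweep caller

A window qualifies when all three hold:

1. ROD at or above the empirical upper 1% quantile of all non-missing
   window ROD values (`rod_tail = 0.01`), computed genome-wide per
   comparison with linear interpolation (R's default quantile type);
2. Tajima's D of the domesticated population below a fixed −2
   (`d_threshold`); a lower-tail quantile alternative is available via
   `d_tail`, since a tail criterion is the other natural reading — the
   fixed value is the default because it is stated first and
   unambiguously;
3. FST above 0.3 (`fst_threshold`).

Windows with any missing statistic never qualify. Qualifying windows
that overlap or abut are unioned into maximal regions, and regions
whose span is not *strictly* greater than `min_span` (default 100 kb,
a literal reading of "spans all >100 kb") are discarded. Region
coordinates are reported as the explicit `[start, end)` of the merged
windows. Sweep sets from different comparisons can be intersected
(`intersect_sweeps`) to ask whether two domesticated lines share
targets.

## LD: decay curves and pruning

Pairwise LD is the squared Pearson correlation of genotype dosages
(composite r²), which needs no phase and matches the common tools'
default. The decay curve bins all intra-contig pairs up to `max_dist`
(default 300 kb) by separation; dense panels are thinned to every
k-th site (`thin_to`, default 2000 per contig), which preserves the
distance structure while keeping the pair count tractable. The
half-decay distance is where the curve first drops to half its maximum
bin mean, linearly interpolated between adjacent occupied bin
midpoints — an interpolation rule of this package's own construction,
needed because reported half-decay distances can fall inside a single
bin.

Pruning follows the conventional PLINK 50-SNP/10-SNP/r²>0.2 recipe:
within each window of 50 kept sites advancing by 10, the member of the
worst violating pair with the higher missingness (ties: larger
position) is removed. A banded verification sweep then guarantees the
post-condition that no window of 50 consecutive kept sites retains a
violating pair. Only the SNP-count window mode is implemented: at the
densities this analysis assumes, a literal 50-bp window almost never
contains two SNPs.

## Quality control

Individual-level QC removes, in order, each sample with one primary
reason:

1. **Sex discordance.** The method-of-moments inbreeding coefficient
   $F = (O_\mathrm{hom} - E_\mathrm{hom}) / (L - E_\mathrm{hom})$ is
   computed on Z-chromosome sites with every call treated as
   diploid-coded. In a ZW system the female is hemizygous on Z, so her
   diploid-coded calls are all homozygous ($F \approx 1$) while a true
   ZZ male shows ordinary heterozygosity ($F \approx 0$). A declared
   female is flagged when $F < 0.8$ and a declared male when
   $F > 0.2$ — the thresholds attach to the hemizygosity expectation
   of each sex. Unknown-sex samples are never flagged; values in the
   0.2–0.8 band are noted indeterminate. The check must run before
   hemizygous collapsing (read with `z_contig = NA`, or on a simulator
   panel), because collapsing by the declared label destroys the
   heterozygosity evidence. $F$ uses cohort-wide allele frequencies,
   as the standard tools do; on a strongly structured cohort the
   Wahlund effect inflates male $F$, so sex checks are best run within
   a line — which is also how case/control panels are assembled.
2. **Missingness** above 10%.
3. **Relatedness.** For each pair with mean IBS
   $\overline{(2 - |d_i - d_j|)/2} > 0.9$, the member with higher
   missingness is removed. IBS is evaluated on common sites
   (MAF ≥ 0.05): on a rare-allele-heavy panel, unrelated samples share
   reference homozygotes at most sites and IBS saturates.

SNP-level QC then removes sites in order: missing rate > 0.05;
differential case/control missingness at P < 0.05 (a two-proportion
chi-square by default — asymptotically equivalent to the t test on the
binary indicator and defined in zero-variance cases; a literal t-test
mode exists); minor allele frequency < 0.05; and exact Hardy–Weinberg
P < 1e-4. The HWE test enumerates all heterozygote counts compatible
with the observed allele counts and sums the probabilities of
configurations no more probable than the observed one; it is assessed
in controls only (cases can deviate through association) and over
diploid calls only, since hemizygous genotypes violate its premises.

The centered relatedness matrix
$K = m^{-1} \sum_i x_i x_i^\top$ (mean-centered dosage vectors,
missing calls mean-imputed) is provided for use as the covariance of
an external mixed-model association tool; it is positive semidefinite
by construction.

## Association and the conditional haplotype test

The per-SNP P-value provider is the Cochran–Armitage trend test on
dosage scores with Bonferroni adjustment over the tested sites. A
linear mixed model is deliberately not re-implemented: the package's
contribution is the clumping and haplotype-permutation stage, and the
kinship matrix is exported for users who want an LMM's P-values
instead — the downstream stages accept any P-value column.

The index SNP is the minimum adjusted-P site (ties: smaller position).
Sites within ±100 kb of it (the "flanking 100-kb region" is read as a
200-kb window centered on the index) joining r² > 0.7 with adjusted
P < 0.01 form the clump. Clump genotypes are phased by
Excoffier–Slatkin EM over the diplotype-compatible haplotype pairs of
each individual (frequency convergence tolerance 1e-6, site cap 25,
individuals with missing clump calls excluded, hemizygous individuals
contribute one directly observed chromosome); each individual is
assigned its maximum-posterior pair. The test statistic is the
chi-square of the haplotype-by-phenotype chromosome-count table,
haplotypes below 1% frequency pooled into "other"; its reference
distribution comes from phenotype-label permutations at the individual
level with the phase held fixed, and
$p = (b + 1)/(n_\mathrm{perm} + 1)$ with $b$ the number of permuted
statistics at or above the observed one (ties count as exceedances,
the conservative convention). The default is 5,000 permutations.

## The synthetic-data generator

The simulator is frequencies-first rather than coalescent: it
constructs exactly the statistical structure the scan consumes, at
desk scale, with every planted quantity recorded in a truth ledger.

* **Sites and frequencies.** Site count per contig is
  $L\,\theta\,a_1(2N)$; ancestral frequencies follow the neutral
  $1/i$ spectrum. Per-population frequencies come from the
  Balding–Nichols beta construction with drift $F$ (defaults: 0.01
  wild, 0.05 per domesticated line, reproducing the wild >
  domesticated diversity ordering and the domesticates' positive
  genome-wide D after bottleneck-like drift).
* **LD.** Each population has a founder pool (default 30 haplotypes).
  Carriers of a site are the leading founders of a permutation that
  evolves by random transpositions along the contig, so neighbouring
  sites have nested carrier sets; sample chromosomes are founder
  mosaics with an exponential switch process. `switch_rate_per_bp`
  (default 1e-3, half-decay of a few hundred bp — the rapid-decay
  regime of high-diversity galliform panels) controls both.
* **Sweeps.** A planted sweep fixes all but a few "escaped"
  chromosomes onto one background haplotype; the escaped count is the
  integer whose between-pair fraction best matches the target
  $\pi$ ratio of $1 - \mathrm{reduction}$, so the planted reduction is
  controlled rather than left to Bernoulli noise. Escaped chromosomes
  keep their drifted alleles and surface as rare variants; `sfs_skew`
  adds young mutations as singletons on the swept background at
  per-site rate $\mathrm{skew}\,(1 - \mathrm{reduction})$. Both
  mechanisms push Tajima's D strongly negative, the behaviour the
  D-criterion of the sweep caller relies on. `reduction = 0` is the
  neutral control.
* **Sex system.** ZW with hemizygous female Z; sexes alternate within
  population. A ZW female's Z genotypes are written to VCF as
  diploid-coded homozygotes, as variant callers emit them; reading
  with `z_contig` set restores ploidy 1.
* **Trait.** Carriage of the derived allele at the causal site of a
  configured block (the block site with pooled frequency nearest 0.3)
  makes a sample a case with probability `penetrance`, non-carriers
  with `phenocopy`. True phase at the block sites is stored in the
  truth ledger for phasing-recovery scoring.
* **Missingness** is uniform per call (default 2%).

What the generator does **not** emulate: recombination-rate and
mutation-rate heterogeneity, callability gaps, genotyping error (as
opposed to missingness), background selection, gene conversion,
realistic site spectra under demography beyond Balding–Nichols drift,
and linked-read phase information. Passing recovery tests on this
generator therefore demonstrates that the estimators and the caller do
what they claim on data with the assumed structure — not that the
thresholds are optimal for any particular real genome.

## Numerical and reproducibility choices

* Quantiles use R's default linear interpolation (type 7).
* FST windows with no polymorphic site, ROD with $\pi_\mathrm{wild}=0$,
  D with $S = 0$, r² on monomorphic subsets, and degenerate haplotype
  tables are all reported missing, never zero-filled.
* Deterministic tie-breaks throughout: LD pruning and IBS removal drop
  the higher-missingness member, then the larger position / later
  column; the index SNP takes the smaller position.
* All pipeline randomness derives from one root seed fanned out per
  stage via `substream_seed()`; reruns with the same config and seed
  are byte-identical (checksummed manifest).
* Test and example problem sizes — 2-Mb contigs, 10/11/10 samples,
  $\theta = 0.005$/bp — were chosen so a full scan of a simulated
  genome takes seconds while windows still hold hundreds of SNPs;
  the sweep-recovery study uses ten 2 × 2 Mb genomes with one planted
  200-kb sweep each.

## Known limitations

* The trend test ignores relatedness; on structured case/control
  panels, feed externally computed mixed-model P-values into the
  clumping stage instead.
* EM phasing enumerates diplotype-compatible pairs and is capped at 25
  sites and 16 heterozygous sites per individual; very weakly linked
  clumps can phase poorly, which the permutation test inherits.
* Window-mean chromosome counts make $\theta_w$ and D slightly
  approximate under highly uneven missingness.
* Multi-population (>2) FST, haplotype-based sweep statistics
  (EHH/iHS/XP-CLR) and composite-likelihood callers are out of scope.
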