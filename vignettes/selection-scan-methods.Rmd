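---
title: "Methods: selection scans, ROH, LD and structure in popgenscan"
author: "popgenscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans, ROH, LD and structure in popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

popgenscan implements the downstream analysis of a small whole-genome
resequencing panel — the kind of study that resequences a handful of
livestock or bird breeds at 5–10x, calls a few million SNPs, and asks
which genomic regions differentiate the breeds, how inbred each breed
is, and how linkage disequilibrium decays.  The pipeline starts at a
multi-sample VCF (read alignment and variant calling are upstream and
out of scope) and carries the data through SNP filtering, a windowed
differentiation-and-diversity sweep scan, runs-of-homozygosity
detection, LD-decay estimation, and population-structure summaries.

Because panels like this are rarely redistributable, the package ships a
simulator whose ground truth makes every stage testable; all statistical
claims made here are the ones the test suite and the acceptance script
actually compute.

## The genotype model

A `geno_matrix` holds biallelic SNPs as alternate-allele dosages (0, 1,
2, `NA` for missing) with variant coordinates, phred site qualities,
optional per-sample depths, a sample-to-population map and scaffold
lengths.  All intervals are 0-based half-open internally; VCF, BED and
GFF3 conventions are converted at the I/O boundary.  Any genotype
containing a `.` in its GT field is treated as fully missing, and
multiallelic records are dropped on input.

## SNP filters

Three standard resequencing filters, each idempotent and applied in a
fixed order by `filter_snps()`:

* **Quality** — keep sites with phred quality ≥ 20 (Q20 is exactly a 1%
  error rate, so the boundary is inclusive).
* **Spacing** — a greedy left-to-right scan per scaffold keeps the first
  SNP and every SNP at least 5 bp from the last *kept* SNP.  The greedy
  rule is deterministic and independent of site quality; that is the
  simplest rule satisfying "separated by at least 5 bp".
* **Depth** — the per-site mean depth across samples must fall within
  `[low, high]` × the genome-wide mean.  Published pipelines state this
  rule in several inequivalent ways ("1-, 3-, or 5-fold the average
  depth"), so the two multipliers are configuration, defaulting to
  (1/3, 3).  The reference mean is computed once and cached on the
  object so that re-applying the filter, or filtering scaffolds
  separately against a shared mean, gives identical results.

## The sweep scan

The scan contrasts a *target* population against a *control* in sliding
windows of 40 kb advanced by 20 kb (both configurable), anchored at
coordinate 0 of each scaffold; the final window of a scaffold may be
truncated.

**Differentiation.** Per locus we compute the Weir & Cockerham (1984)
variance components $a$ (among populations), $b$ (among individuals
within populations) and $c$ (within individuals) from the per-population
sample sizes $n_i$, allele frequencies $p_i$ and heterozygote
proportions $h_i$.  A window's $F_{ST}$ is the ratio of sums
$\sum a / \sum (a+b+c)$ over its usable loci — Weir & Cockerham's
recommended multi-locus combination, markedly more stable than averaging
per-locus ratios in windows with few SNPs.  Negative window values are
an expected property of the estimator and are retained in quantile
computations.  Loci where a population has no called genotype, or where
the mean sample size is ≤ 1, are excluded; loci monomorphic across all
populations contribute exactly zero.  The implementation is checked
against an independently coded scalar transcription of the formulas on
randomized genotype tables (agreement to 1e-12) and on closed-form cases
(a fixed difference gives exactly 1).

**Diversity.** Per-site nucleotide diversity within a population is the
unbiased heterozygosity $\pi_{site} = 2 c_{ref} c_{alt} / (n(n-1))$ with
$n$ the number of called alleles; window $\theta_\pi$ sums the sites and
divides by the window span in bp.  The per-bp denominator cancels in the
ratio below and matches the common windowed-$\pi$ convention.  Sites
with fewer than two called alleles contribute zero.

**Joint outliers.** Windows are ranked by $F_{ST}$ and by
$\log_2(\pi_{control}/\pi_{target})$, oriented so that diversity *loss*
in the target is positive.  A window whose target diversity is exactly
zero while the control's is not receives $+\infty$ — the strongest
possible signal, ranked above all finite values rather than dropped; a
window where both are zero is unusable, as are windows with fewer than
10 usable SNPs (configurable) or a zero $F_{ST}$ denominator.  The
top-5% threshold for each statistic is the smallest of the top
$\lceil q\,n \rceil$ order statistics over usable windows, and selection
is "≥ threshold", so exactly the top 5% are taken apart from ties,
which are included; with $q = 1$ every usable window qualifies.  This
nearest-rank convention needs no interpolation and is exactly
reproducible.  Candidate regions are overlapping-or-book-ended outlier
windows merged per scaffold.  At least 20 usable windows are required
before quantiles are computed.

## Runs of homozygosity and F_ROH

`scan_sample()` re-implements the classic PLINK scanning-window
algorithm with the standard parameters as defaults: windows of 50
consecutive SNPs pass when they contain at most 2 heterozygous and 5
missing calls; a SNP is in a homozygous state when at least 5% of the
windows covering it pass (the upstream tool's undocumented default,
exposed as `hit_threshold`); maximal runs of such SNPs — split at
inter-SNP gaps above 1,000 kb — are trimmed to their outermost
homozygous non-missing calls and kept if they contain ≥ 100 SNPs, span
≥ 500 kb and average ≤ 50 kb per SNP.  The algorithm is "PLINK-like":
byte-identical replication of PLINK 1.07 is a non-goal, and the exact
treatment of heterozygotes deep inside a called segment can differ in
corner cases.  On fixtures with dense flanking heterozygosity the
called boundaries are exact; on simulated backgrounds they are within a
few inter-SNP intervals, because a chance run of homozygotes adjacent
to a true tract is legitimately part of the call.

$F_{ROH}$ is the summed ROH length over the total autosome length.
When no autosome table is given, scaffold spans observed in the data are
used with a warning; segments on scaffolds absent from a provided table
are a hard error.

## LD decay

$r^2$ between two loci is computed from unphased genotypes by estimating
two-locus haplotype frequencies with an EM over the 3×3 genotype table:
only the double-heterozygote cell is phase-ambiguous, and its expected
split is re-estimated each iteration.  The EM starts at linkage
equilibrium and stops when the log-likelihood changes by less than
1e-10 (at most 1,000 iterations); the log-likelihood is non-decreasing
by construction and asserted in tests.  When a table has no double
heterozygotes the haplotypes are counted directly — an exact shortcut
the EM provably agrees with.  The decay curve takes all intra-scaffold
pairs within 500 kb whose minor-allele frequencies are ≥ 0.05, bins
them by distance (1 kb default), and averages $r^2$ per bin, pooling
across scaffolds weighted by pair count.  A `max_pairs` cap subsamples
pairs uniformly for genome-scale inputs; since the cap samples pairs,
not distances, bin means are unbiased.

A useful calibration: for $n$ diploid samples, independent loci have
mean $r^2$ of order $1/(2n)$, so LD signals must be read against that
finite-sample floor — halving the sample inflates it, which the tests
check directly.

## Population structure

* **Distance** — allele-sharing distance
  $d(i,j) = \mathrm{mean}\,|g_i - g_j|/2$ over loci called in both
  samples: 0 for identical genotypes, 1 for opposite homozygotes.  (The
  sequence-based distance used by some published pipelines is not
  defined for SNP dosage input; allele-sharing is the standard
  substitute and is stated here explicitly.)
* **Tree** — Saitou–Nei neighbor joining via the ape package, exact on
  additive matrices (verified to 1e-9 on matrices generated from random
  trees).  Negative branch lengths are clamped to zero with the deficit
  moved to the sister branch, preserving path lengths through the
  parent.  Bootstrap support resamples *loci* with replacement — the
  standard unit for distance bootstraps — recomputes distance and tree,
  and reports the percentage of replicates containing each internal
  bipartition of the full-data tree.
* **PCA** — EIGENSOFT-style normalisation
  $m_{ij} = (g_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$ with $p_j$ the sample
  allele frequency; monomorphic loci are dropped, missing entries are
  imputed to the post-centering mean (zero), and the sample covariance
  is eigendecomposed.  Coordinates are eigenvectors scaled by the square
  roots of their eigenvalues.

## Gene annotation and overlap

Candidate regions are intersected with gene models (BED4+ taken as
half-open; GFF3 `gene` features converted from 1-based inclusive;
mRNA/exon children ignored — reporting is at gene resolution).  A gene
counts if it overlaps any region by ≥ 1 bp (a minimum-overlap fraction
is available for sensitivity analysis); a gene ending exactly where a
region starts does not overlap, by the half-open convention.  For
several contrasts, `overlap_sets()` reports the count of genes in
*exactly* each combination of contrasts — the numbers a Venn or upset
diagram displays — plus the all-contrast intersection; the
exact-combination counts always partition the union.

## The simulator

`simulate_populations()` draws, per SNP, an ancestral frequency
$p \sim U(0.05, 0.95)$ and per-population frequencies from the
Balding–Nichols distribution
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, whose single parameter $F$
*is* the expected $F_{ST}$ — which makes recovery tests
self-calibrating.  Bounding $p$ away from 0 and 1 keeps most sites
polymorphic while still producing occasional monomorphic draws, which
are deliberately retained to exercise degenerate-site handling.
Genotypes are either independent binomial draws from the population
frequency (`recomb_rate = 0`, the default — the unlinked regime the
$F$-recovery analyses assume) or mosaics copied from 20 founder
haplotypes per population with recombination breakpoints.  The mosaic's
switch rate is an *effective*, population-scaled rate standing in for
many generations of recombination: around `1e-5`/bp it yields an
$r^2$ decay scale of roughly 100 kb, decaying from about
$1/k_{founders} + 1/(2n)$ between tight loci toward the $1/(2n)$ noise
floor at long range.  A per-meiosis magnitude (~1e-8) would produce no
measurable decay over Mb scales and is not what this parameter means.

Defaults emulate the study conditions the package targets: two or more
populations of 8 diploid samples, scaffolds of a few Mb, SNP density
0.005/bp (the genome-wide rate of a ~5–10x panel carrying roughly five
million SNPs on a ~1.1 Gb genome), Poisson read depth with mean 8,
site qualities with a realistic left tail below Q20, and 1% missing
calls.  `inject_sweep()` drives a chosen fraction of interval SNPs to
fixation for the target population's majority allele (diversity loss
plus differentiation gain — the signature of a strong sweep);
`inject_roh()` replaces a sample's heterozygotes in an interval with
random homozygotes, the dosage-level analogue of copying one haplotype
over the other.  Both record their intervals in a truth object that
serialises losslessly to TSV.

What the simulator does *not* model: demography (bottlenecks,
migration, admixture), mutation-rate heterogeneity, genotyping error
correlated with depth, and haplotype structure beyond the founder
mosaic.  Passing the recovery tests therefore demonstrates estimator
correctness and pipeline wiring under idealised sampling noise — not
robustness to demographic confounding, which no simulation this simple
can establish.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the
statistical checks are sharp but cheap: $F$ recovery uses 2×50 samples
and 20,000 SNPs over 20 seeds per $F \in \{0.05, 0.1, 0.2\}$ (observed
|bias| well under 0.005); sweep detection uses a 5 Mb genome, 2×8
samples, a 200 kb sweep at intensity 0.9 on an $F = 0.05$ background
over 20 seeds; LD uses 16 samples on 1.5 Mb with 30,000 subsampled
pairs over 10 seeds; ROH uses a 3 Mb scaffold with SNPs every 4 kb.
Determinism is end-to-end: a fixed seed makes simulator output, and
every pipeline file, byte-identical across reruns.

Other numerical choices worth stating: EM convergence at 1e-10 absolute
log-likelihood change; $r^2$ clamped to [0, 1] against rounding;
quantile thresholds by nearest rank (no interpolation); truth tables
written with 17 significant digits so they round-trip exactly; ROH
density checked as kb-per-SNP over the whole segment, matching the
parameter's unit.

## Limitations

The ROH caller is PLINK-like, not PLINK-identical.  The LD pair
subsample trades pair-level completeness for runtime on dense inputs.
The NJ/PCA stages use all loci by default (no LD pruning); an
LD-pruned or thinned analysis can be had by filtering the matrix first.
Ancestry-fraction estimation, haplotype-based sweep statistics
(iHS/XP-EHH), functional enrichment, and anything upstream of the VCF
are out of scope.
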