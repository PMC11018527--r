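---
title: "Methods: subgenome dynamics and population genomics with polykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome dynamics and population genomics with polykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polykit)
```

polykit analyses recently formed allotetraploids whose two subgenomes
(called CC and EE throughout, after their diploid progenitor genomes) are
similar enough to recombine occasionally but distinct enough that short
reads can be assigned to a subgenome. It covers four analysis layers —
homoeologous exchange (HE) detection from read depth, fractionation
statistics over syntelog tables, a population-genetic statistic suite, and
subgenome expression bias — plus a synthetic-data generator that emulates
every input with recorded ground truth. This vignette explains the models,
the tunable parameters, and the numerical choices, and states what the
synthetic world does and does not establish.

## Homoeologous exchange from read depth

At a tetraploid locus an accession carries four homoeolog copies, normally
2:2 across subgenomes. A crossover between homoeologous chromosomes changes
the dosage (3:1, 4:0, ...), which is visible as a coverage imbalance
between the CC-side and EE-side copies of a syntelog pair. With window
means of per-gene depth, the allele balance is

\[ A = 4\left(\frac{CC}{CC + EE} - 0.5\right), \]

so \(A = 0\) at 2:2, \(\pm 1\) at 3:1/1:3 and \(\pm 2\) when one subgenome
is absent. Windows are 10 genes wide with step 1 (the step is our choice;
the window width is the field convention); \(A\) is scale-invariant, so
mean depth differences between accessions do not matter. Classification
uses the published thresholds: \(|A| > 1.5\) homozygous, \(|A| < 0.5\)
balanced; the unnamed bands \(0.5 \le |A| \le 1.5\) are labelled
`CC_biased`/`EE_biased` because the 3:1 tests need them.

`segment_dosage()` turns window classes into segments: runs shorter than
`min_windows` (default 5) are absorbed into the balanced background, and
segment boundaries are reported at window centers. The center convention is
deliberate: a window straddling a true breakpoint switches class when about
half of its genes have switched dosage, so centers are unbiased breakpoint
estimates, whereas window-start/window-end spans overshoot by half a window
on each side. One windowing artifact needs explicit handling: at the edge of
a homozygous (4:0) segment, windows ramp through the biased band and create
a spurious sub-window "biased" run. Runs of biased class no longer than one
window that sit next to a homozygous run of the same direction are split at
their midpoint between that class and balanced. A consequence, and a known
limitation, is that a genuine 3:1 tract shorter than one window directly
abutting a 4:0 tract will be absorbed into it.

Dosage tests follow the published convention: observed CC/EE counts
(window-summed integerized depths as a read-count proxy; raw counts can be
supplied) against a 3:1 expectation with a one-degree-of-freedom
chi-squared statistic, Bonferroni-corrected with significance at adjusted
p < 0.0005. Whether counts are tested per segment or genome-wide per
accession is exposed through `n_tests`.

## Fractionation statistics

Post-polyploidy gene loss proceeds by excision of runs of consecutive
genes. `deletion_run_spectrum()` counts maximal same-side deletion runs per
subgenome (never across block boundaries); `intergenic_gap_profile()`
measures, for each run length L, the bp between the flanking retained genes
on the deleted side against the same ancestral span on the retained side.
The synthetic generator does not contract coordinates on deletion (the gene
model is lost, the DNA span stays), so in the synthetic world a run of
length L spans exactly `L*gene_bp + (L+1)*intergenic_bp` on both sides —
which is also the closed form the tests check. How the real analysis
normalizes "unfractionated" spans is not fully specified in the source
material; we compare matched ancestral spans.

Retention tracks are sliding windows over ancestral gene order (default
unit: genes, matching the 10-gene HE convention; a trailing partial window
keeps its true gene count). Retention-by-origin enrichment cross-tabulates
genes in the high-retention stratum (window value at or above the 0.8
sample quantile; the low stratum uses 0.2 — the source states the
enrichment but not the cut, so both are free parameters) against
WGD-origin, with a two-sided Fisher exact test and the sample cross-product
odds ratio.

Ks peaks use a Gaussian KDE with Silverman's rule-of-thumb bandwidth on a
512-point grid over `[0, max(ks)*1.05]` — the defaults of the density
function the field uses — so peak positions are reproducible; all local
maxima are returned sorted by density. LTR insertion ages use
`T = d/(2 * rate)` with the conventional rate 1.3e-8 substitutions per site
per year; a Jukes-Cantor pre-correction is available but off by default,
matching common practice for young insertions.

## Population statistics

Nucleotide diversity: per site \(\pi = 2p(1-p)\,n/(n-1)\) with `n` the
non-missing haplotype count, summed per window and divided by the window
span in bp (monomorphic positions contribute zero). Defaults are 100-kb
windows with 10-kb steps; the genome value is the mean of window values.
Tajima's D uses the 1989 constants computed from the sample's haplotype
count, windows of 100 kb (non-overlapping by default; whether the original
analysis overlapped them is unstated), and windows without segregating
sites are excluded from the mean.

F_ST is Weir & Cockerham (1984) theta. Two combinations are exposed
because they answer different questions: `gene_fst()` averages per-site
theta over the gene span ±2 kb (the per-gene scan convention), while
`wc_fst_global()` uses the multi-locus ratio of summed components. The
distinction matters: under the neutral frequency prior most variants are
rare, per-site ratios at rare variants are strongly biased toward zero, and
the mean-of-ratios underestimates a planted Balding–Nichols F = 0.2 at
about 0.13, while the ratio-of-sums recovers 0.20. Recovery/calibration
claims in the tests therefore use the ratio-of-sums.

F3(target; A, B) is the mean over sites of \((t-a)(t-b)\) with sample
frequencies; negative values indicate admixture. Because \(\hat t\) appears
in both factors, the raw product carries a \(+\mathrm{Var}(\hat t)\) bias
at every site; with genome-scale site counts this drives the null Z
arbitrarily positive regardless of sample size. The default therefore
subtracts the standard unbiased heterozygosity term
\(\hat t(1-\hat t)/(n_t-1)\) per site (`het_correction = TRUE`; the raw
product remains available). Standard errors come from a weighted
delete-one-block jackknife (blocks of 20 kb, weights proportional to block
site counts, the Busing et al. 1999 weighted formulas), and Z = estimate/SE
(undefined and flagged when the SE is zero or fewer than two blocks exist).
Z-score FDR adjustment converts lower-tail Z to p (negative Z is the
signal), applies Benjamini–Hochberg, and maps back through the normal
quantile; the adjustment is monotone and never more extreme than the input.

The introgression scan computes frequency-based ABBA/BABA D (and the
dynamic-donor f_d of Martin et al. 2015) in non-overlapping 20-kb windows
with the same weighted jackknife genome-wide. The distance-fraction
statistic used in part of the original analysis is defined in a cited
reference and is deliberately not guessed here.

Ancestral states are the majority allele across outgroup haplotypes; ties
are unresolved, and unresolved sites are excluded from (and counted
against) the unfolded SFS. Outgroups are modeled as genotype columns — the
original procedure votes over reads; with called genotypes the vote is the
same computation at the call level. Time scaling uses a 21-year generation
time, with ka rounded half-away-from-zero to one decimal (1,450 generations
→ 30.5 ka).

## Expression bias

Expression is compared on the published log scale, `log10(x + 1e-4)`, so
zero TPM maps to exactly −4. A pair is CC- or EE-biased when its mean log10
CC/EE ratio reaches `log10(fold_threshold)` (default fold 2). The global
dominance test is an exact two-sided binomial sign test of CC- versus
EE-biased counts against 0.5 — the original's exact procedure lives in its
supplementary material, so this simple exact test is our construction,
flagged as such. Family summaries flag a family as mosaic when it contains
at least one pair biased in each direction.

## The synthetic world

All generators are driven by one validated configuration (`sim_config()`)
and a single seed; identical configurations give byte-identical fixture
files. Defaults describe the stated world of the tests: ~40x coverage
(negative binomial, size 20 — overdispersed like real short-read data; the
true depth law over syntelogs is unknown, NB is our choice), 1,000-bp genes
with 500-bp spacers, geometric excision runs (p = 0.5, mean 2 genes),
retention 0.95 on arms versus 0.6 in a 30% pericentromeric span, the five
integer dosage classes for planted HE, Balding–Nichols population structure
around a neutral 1/p ancestral frequency prior (with the exact discrete
1/i construction when F = 0, which makes the expected unfolded SFS exactly
neutral and Tajima's D centred on zero), outgroups fixed for the ancestral
allele up to a configurable error, per-call missingness, and log-normal
expression (baseline meanlog 2, sdlog 1; log-scale noise sd 0.2) with
planted fold-4 bias in a configurable fraction of pairs.

What a green test establishes: the estimators recover the signals this
world plants, at the stated sizes and depths, and the statistics match
independent oracles exactly. What it does not establish: robustness to
mapping bias between subgenomes, reference bias, depth waves (GC,
replication timing), linkage disequilibrium (sites are exchangeable given
their frequencies — block jackknife SEs are calibrated here precisely
because sites are independent, and real LD makes blocks the right unit,
not smaller), selection, or sample-level dropout. Planted truth is recorded
once per signal and read only by tests.

## Numerical and degenerate-input conventions

Zero-coverage windows give undefined A (`no_data`); degenerate Fisher
tables (any zero margin) are flagged with p = 1 and an undefined odds
ratio; the 3:1 test refuses zero totals; Tajima's D needs at least four
haplotypes and one segregating site; LD pruning keeps the earlier site of
a correlated pair (deterministic); unfolded SFS entries plus exclusions
always sum to the segregating-site count. Coordinates are 1-based inclusive
in memory (VCF/GFF3 convention) and 0-based half-open on BED output.
Fisher and binomial p-values are the standard minimum-likelihood two-sided
definitions and are tested against full enumeration.
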