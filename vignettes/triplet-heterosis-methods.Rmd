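---
title: "Methods: triplet transcriptome analysis of heterosis"
author: "hetriplet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplet transcriptome analysis of heterosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetriplet)
```

## The design and the questions

`hetriplet` analyses half-diallel parent–hybrid experiments: a set of
inbred lines (four by default, named after the maize lines of the
ear-length study the package models) is crossed pairwise without
reciprocals, giving one hybrid per unordered pair — six hybrids from four
parents — so each line takes part in several parent–parent–hybrid
*triplets*. Two questions drive the analysis. First, which genes make one
parent transmit a superior *additive* effect to all of its hybrids?
Second, which genes deviate in the hybrid from the mid-parent expectation
(*non-additive* expression) and might therefore carry heterosis — the
superiority of the hybrid over both parents? A third axis,
allele-specific expression, asks whether the two parental alleles of a
gene are expressed unequally inside the hybrid, the signature of
cis-regulatory divergence.

## Phenotype statistics

Mid-parent heterosis is `MPH = 100·(F1 − MP)/MP` with
`MP = (P1 + P2)/2`; `mph()` rounds half-up to two decimals because that
is how such percentages are printed in phenotype tables (base `round()`
rounds half to even, which cannot reproduce printed values like 75.00
from 74.995). `lsdGroups()` runs a one-way ANOVA and assigns Fisher's LSD
letters by the standard sweep on means sorted descending: each maximal
run of mutually non-different lines gets a letter, and runs contained in
another are absorbed. With unequal replicate numbers, the sweep checks
only run endpoints; the grouping is exact for balanced designs, which is
the intended use. `deltaDeltaCt()` is the textbook qPCR statistic.

## Quantification

`summarizeLibraryQC()` is deliberately plain arithmetic —
`100·clean/raw` and `100·mapped/clean`, half-up to two decimals — because
its job is to reproduce published QC tables exactly, including their
totals row. The study-wide mapped rate in such tables is the *mean of the
per-library rates*, not the ratio of the summed reads (the two differ in
the second decimal); the package computes both and the tests pin down
which one the printed average is.

`sizeFactorsMedianRatios()` is median-of-ratios normalization: the
per-gene reference is the geometric mean across samples over genes with
strictly positive counts everywhere, and a sample's factor is the literal
median of its count/reference ratios. When no gene is positive in every
sample the function stops rather than silently switching to a
pseudo-reference — with 20 samples that situation signals a data problem.
Note two small, deliberate properties: factors are defined only up to a
common scale (so scaling one sample by *c* scales its factor by *c*
relative to the others, not absolutely), and the even-count median is
interpolated on the ratio scale, where reference implementations that
work in log space interpolate geometrically; the two agree to ~1e-4 on
typical matrices.

FPKM is `count·10⁹/(length·mapped total)`. Replicate correlation is
Pearson on `log2(normalized + 1)` — the transform is the package's
choice, made because correlations on raw counts are dominated by the few
most-expressed genes. Per-line expression is the arithmetic mean of the
(two) replicates.

## The negative-binomial differential test

`testDifferential()` compares two groups of replicate columns under
`Var = μ + αμ²`. Per gene it reports normalized means, the pseudocounted
fold change `log2((m2+1)/(m1+1))` (finite even for all-zero groups), a
Wald statistic on the difference of log means with delta-method variance
`1/(n(m+1)) + α/n` per group, a raw p-value, a BH-adjusted q-value for
transparency, and the joint call `isDEG = (p < 0.05) & (|log2FC| > 1)` —
raw p, because the joint criteria, not an FDR rule, define the call.

Dispersion is the part that needed a real decision. With two replicates
per group, a per-gene method-of-moments estimate carries about one degree
of freedom, and a Wald test built on it has type-I error near 0.16 at
nominal 0.05 — unusable. The package therefore keeps the per-gene
moment estimates but smooths them with a parametric mean-dispersion
trend, `α(μ) = a0 + a1/μ`, fitted by least squares across all genes
(winsorized at the 1st/99th percentiles to tame the heavy-tailed raw
estimates), and uses the trend value in the test. On simulated null data
at `μ = 100`, `α = 0.05`, `n = 2 + 2` this brings the measured type-I
error to ≈ 0.053. The cost is an assumption: genes at the same mean share
a dispersion. The simulator generates data that satisfy it exactly; real
data do not quite, and genes with unusually high biological variability
will be anticonservative. This borrowing-across-genes strategy is the
same trade made by the established NB differential packages at small n.

## Mid-parent construction and pattern classes

The hybrid-vs-mid-parent comparison needs replicate-level MP values to
power the same NB test, so `buildMidparentPseudosamples()` pairs
replicate *i* of each parent and takes the rounded mean of their
normalized counts; the pseudo-samples are already normalized, so their
size factors are one. A gene is *non-additive* when the hybrid-vs-MP
comparison meets the joint criteria; additive and non-additive therefore
partition the tested genes by construction.

`classifyPatterns()` then refines non-additive genes using the
hybrid-vs-parent tests, with high/low parent decided per gene from the
normalized line means (so labels cannot depend on the order the parents
are passed in): over-dominance means significantly above the high
parent, under-dominance significantly below the low parent, high/low
parent dominance means indistinguishable from one parent while
differential from the other, and anything else is `ambiguous` so the
classifier is total.

One consequence of the joint criteria deserves emphasis: a hybrid
sitting *exactly* on a parent can never be called non-additive, because
`|log2(2h/(h+l))| < 1` for any finite parental ratio. Exact dominance is
therefore invisible to this analysis; the dominance labels are reachable
only for hybrids strictly between a parent and the over/under-dominance
region. The simulator's truth tables record the generative mode per
hybrid so tests can distinguish "planted" from "callable", and the
planted-recovery validations use over/under-dominance modes, which are
identifiable at the configured deviations.

The parental-range partition is a separate, descriptive classification:
inclusive bounds on replicate-averaged line means, no significance
filter, summarized as counts and half-up percentages that add to 100 up
to rounding.

## Allele-specific expression

`assignReads()` applies an all-or-nothing rule to SNP match profiles: a
read belongs to a parent only if *every* informative SNP it covers
(parental alleles differ) matches that parent; reads covering no
informative SNP are ambiguous and mixed-evidence reads are conflicting —
both are excluded from the counts rather than fractionally assigned.

`callASE()` treats "deviation from 1:1 validated by 1000 permutations"
as a Monte-Carlo binomial test, since nothing else is exchangeable in a
two-column count table: the allele columns are normalized by
median-of-ratios factors computed on the two columns over sufficiently
deep genes, and for each tested gene B draws from Binomial(n, 1/2)
estimate `perm_p = (1 + #{|X_b − n/2| ≥ d_obs})/(B + 1)`. The +1 keeps
p ≥ 1/(B+1), the attainable floor; this floor matters in practice —
with B permutations, BH at 0.05 can never select from a table larger
than about `0.05·B·R` genes however extreme the imbalance, so B should
scale with the table. Genes below `minDepth` (default 10 informative
reads; the depth filter is the package's choice) are returned untested,
never silently p = 1. BH across tested genes gives `fdr_q`, and
`is_ase ⇔ fdr_q < 0.05`.

The permutation scheme is validated against the exact two-sided binomial
distribution: rank correlation with exact p-values exceeds 0.99 on null
tables, and the empirical CDF of `perm_p` tracks the exact null CDF
evaluated at the midpoints between its atoms (evaluating at the atoms
themselves would count half of each atom's symmetric Monte-Carlo smear as
missing mass).

## Comparative set logic and enrichment

`candidateAdditiveGenes()` encodes the focal-pair chain: genes
differential between the corresponding hybrids in *both* shared
backgrounds, intersected with the parent–parent differential set.
`candidateHeterosisGenes()` intersects the non-additive sets of the three
triplets containing each focal parent, and the two focal results in turn.
`intersectSets()` returns all 2^k − 1 Venn region counts (k ≤ 5), which
always sum to the union. Enrichment is an annotation-agnostic
hypergeometric upper tail, `phyper(k−1, K, N−K, n, lower.tail = FALSE)`,
against a user-supplied gene→term map and an explicit universe (what the
right universe is — expressed genes or the genome — is a modelling choice
the caller must make); raw p < 0.05 with a top-10 report matches how such
analyses are usually summarized, and a BH column is emitted alongside.

A dilution identity governs the additive chain and is worth knowing when
interpreting it: a gene whose focal parents differ by fold `2^d` differs
between the corresponding hybrids by only `(2^d + 1)/2`, because the
shared background allele contributes equally on both sides. For `d = 3`
that is log2 4.5 ≈ 2.17 (comfortably callable); for `d = −3` it is
log2 0.5625 ≈ −0.83 — *under* the fold threshold. Down-regulated focal
genes are thus borderline in hybrid-vs-hybrid comparisons by arithmetic,
not by chance, and the package's validation asserts exact exclusion of
unplanted genes plus recovery of the analytically callable (up-planted)
set.

## The simulator

`simulateTriplets()` generates the study conditions end to end:

- **Scale.** Defaults: 10,000 genes, 2 replicates per line, library sizes
  drawn uniformly on [13, 22] million reads per sample — the scale of a
  typical RNA-seq library in this kind of study. Validation runs in the
  test suite shrink `nGenes`/`librarySizes` proportionally (300 genes ×
  30,000 reads keeps per-gene depth realistic) so the full suite stays
  fast; the acceptance-grade recovery run uses the full 10,000 genes at
  mean depth 200, satisfying the depth ≥ 50 regime the recovery claims
  assume.
- **Expression model.** Per-gene relative abundances are log-normal
  (`meanlog = 4`, `sdlog = 1.5`, a heavy-tailed shape typical of
  transcriptomes; no distributional description of the real data exists,
  so these are explicit stand-ins). Counts are NB with
  `Var = μ + αμ²`, `α = 0.05` by default, per-sample means scaled so each
  sample's expected total equals its library size.
- **Planted differential genes.** A fraction (default 0.1) of genes is
  shifted by `2^(±degLog2FC)` in one randomly chosen parent. Truth
  records the parent and signed effect. Because hybrids inherit the
  mid-parent mean, these genes also drive hybrid-vs-hybrid differences at
  the diluted fold above.
- **Planted non-additive genes.** A disjoint fraction (default 0.05,
  kept disjoint so each truth label isolates one effect) gets hybrid
  means moved off MP: over/under-dominance places the hybrid
  `nonadditiveLog2Deviation` (default 2) log2 units beyond MP and at
  least `overdominanceMargin` (default 0.5, enough to separate classes at
  two replicates) beyond the extreme parent; dominance modes move the
  hybrid to the extreme parent, realized only in hybrids whose parents
  differ for that gene — the truth table records the realized mode per
  hybrid.
- **Allelic counts.** Per hybrid, each gene's informative reads are a
  Beta-distributed fraction of its total (mean 0.3, concentration 10 —
  the fraction of reads overlapping a diagnostic SNP is never published,
  so this is a stated assumption), split binomially at 0.5, or at
  `cisBias` (default 0.8) for the planted cis fraction (default 0.1),
  planted independently of non-additivity so that the small observed
  overlap between ASE and non-additive genes is an emergent check.
- **Gene lengths** are log-uniform on [500, 5000] bp.

What the simulator does *not* emulate: mapping bias toward the reference
allele, gene-wise dispersion heterogeneity, correlated genes, isoforms,
GC effects, or batch structure. Passing the planted-recovery tests
therefore demonstrates that the implementations are correct under the
stated model, not that the thresholds are optimal for real maize data.

## Numerical and interface choices

- Half-up rounding everywhere a printed percentage is reproduced; the
  implementation nudges by one ulp so values stored just below x.xx5 do
  not round down.
- The fold-change pseudocount (+1) and the dispersion floor (1e-8) keep
  every statistic finite; all-zero genes get p = 1 by definition.
- Determinism: `simulateTriplets()` consumes a single seed;
  `runPipeline()` fans its master seed out to fixed per-stage child seeds
  so toggling stages does not shift the streams of the others. Re-running
  with the same configuration reproduces every output byte for byte.
- Errors are loud: unequal replicate numbers when pairing MP
  pseudo-samples, missing comparisons in candidate chains, lines with a
  single replicate in LSD, and undefined QC rates all stop with a named
  message instead of recycling or defaulting.

## Known limitations

- The trend-smoothed dispersion assumes exchangeable genes at equal
  means; outlier-dispersion genes are anticonservative at n = 2.
- The LSD letter sweep checks run endpoints only, exact for balanced
  designs.
- Exact dominance is uncallable under the joint criteria (see above);
  reported dominance classes are partial-dominance hybrids.
- Gene-level ASE aggregates reads across a gene's SNPs; a SNP-level
  variant would detect isoform-specific imbalance but is not
  implemented.
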