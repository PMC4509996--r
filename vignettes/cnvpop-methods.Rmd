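---
title: "cnvpop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cnvpop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

This vignette is the package's own account of the statistics it
implements: what each quantity estimates, which assumptions it makes, what
the tunable parameters mean, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open and a choice had
to be made. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The setting and the data model

The intended input is a read-depth CNV call set from whole-genome
resequencing of unrelated individuals sampled from a few natural
populations: for each individual, a list of duplication/deletion intervals
with an estimated *diploid* copy number (CN), plus gene annotation
(transcription units), segmental duplications (SDs), assembly gaps, and a
sample sheet assigning each individual a population and a sex.

All coordinates are 0-based half-open (BED convention) in every file and in
memory; the annotation formats this package consumes are all BED-family, so
adopting one convention end to end removes a whole class of off-by-one
errors. Chromosome Y is not modelled — analyses cover autosomes and the X,
with the male X hemizygous (baseline CN 1 instead of 2).

Two call-level filters run before anything else:

* **Minimum length 1 kb** (`min_len = 1000`). Read-depth callers are
  unreliable below ~1 kb at typical coverage, and low-coverage samples lose
  small events entirely, which would bias between-sample comparisons.
  "Smaller than 1 kb" is excluded, so a call of exactly 1000 bp is kept.
* **Assembly-gap exclusion**. A call sharing ≥ 1 bp with a gap is removed.
  The strictest reading of "intersecting" was chosen deliberately (and is
  the behaviour `filter_calls()` documents); a bookended call — ending
  exactly where a gap starts — shares zero bases and is kept. Whether the
  original analyses treated bookended calls as intersecting is not
  recoverable; the choice only affects calls abutting gaps to the base.

## CNV regions

A CNV region (CNVR) is a connected component of the call-overlap graph
across *all* individuals on one chromosome; its borders are the outer
coordinates of its member calls. The merge is distance-0: calls that only
abut (end of one equals start of the next) are merged, mirroring the common
interval-merge default of the standard tools. Duplications and deletions
merge together — the CNVR is a locus definition, not a genotype.

CNVRs are partitioned by ≥ 1 bp overlap with SDs longer than 10 kb (larger
SDs are the ones prone to non-allelic homologous recombination). The two
partitions are compared at *call* level: length and log2 haploid copy
number distributions under two-sample Kolmogorov–Smirnov tests, and
presence spectra (number of carriers per CNVR). Absolute deletions (CN 0)
have no logarithm, so haploid values below 0.001 are floored at 0.001,
producing the conventional "−10" bin. A minimum-overlap *fraction* for SD
intersection was considered and rejected: 1 bp is what "intersect" means in
the upstream tools, and the partition is descriptive, not inferential.

## CNV genes and genotyping

A transcription unit is a *CNV gene* when at least one call of at least one
individual contains it completely (call `[a, b)` contains gene `[c, d)` iff
`a ≤ c` and `d ≤ b`). Containment is per call: a gene covered only by the
union of two abutting calls is **not** a CNV gene, because a single
mutational event is what the definition is after. `find_cnv_genes(...,
per_call = FALSE)` relaxes this for users who prefer the union reading.
Pseudogenes and predicted genes are retained if present in the input
annotation; they are copy-number variable and functionally relevant, and
silently dropping them would bias the gene universe of the enrichment
test.

Per-individual gene copy number is the length-weighted average over the
gene body: bases under a call take the call's CN, all other bases the
sex-aware baseline. This mirrors what a read-depth genotyper reports when a
gene partially overlaps calls. Genotypes stay continuous; rounding to
integers (half-up: 1.5 → 2) happens only where an operation needs discrete
CN — allele counting and gene-loss tabulation. Two same-sample calls that
overlap a gene with contradictory CN on shared bases raise an error rather
than averaging silently: that situation signals a malformed callset, and
no answer computed from it would be meaningful.

The SD-association test is a hypergeometric upper tail: of `N` background
genes, `K` overlap large SDs; drawing the `n` CNV genes, `k` overlaps are
observed, and `p = P(X ≥ k)`.

## Population differentiation

### V<sub>ST</sub>

For one gene and two populations, `v_st = (v_t − v_s)/v_t`, with `v_t` the
variance of the pooled copy numbers and `v_s` the sample-size-weighted mean
of the within-population variances. The variance *estimator* is not fixed
by the statistic's usual description, so the package uses the population
variance (divisor *n*) on both paths. This gives the cleanest boundary
behaviour: two identical populations yield `v_st = 0` exactly, and zero
within-population variance yields `v_st = 1` exactly. With divisor *n* − 1
the weighted decomposition no longer telescopes and identical populations
can give small nonzero values. Negative values (within-variance exceeding
pooled variance, common for small samples) are reported, not clipped —
clipping would bias per-pair averages upward. When `v_t = 0` the statistic
is undefined (0/0) and is reported as `NA` with a `defined = FALSE` flag,
never as 0: "no variation anywhere" carries no differentiation signal
either way.

### The divergence scan

Per gene, a one-way ANOVA across populations (populations smaller than
`min_pop_size = 4` are excluded by default — a 3-animal island sample has
too little within-population information and unbalances the design);
Benjamini–Hochberg FDR at `alpha = 0.05` applied **once across all scanned
genes** (not per population pair — the gene is the discovery unit);
retention requires additionally a maximum pairwise difference in population
mean CN of at least `min_mean_diff = 1` copy, which removes
statistically-significant-but-biologically-trivial shifts; retained genes
get Tukey HSD per-pair adjusted p-values (Tukey–Kramer for unequal sizes).
Genes with zero within-population variance have an infinite F; the
studentized range is then degenerate, and per-pair p is reported as 0 where
the pair means differ and 1 where they are equal, so that planted
noise-free cases behave like the limit of vanishing noise.

The scan reports both the FDR-significant count and the post-filter
selected count as attributes, because published analyses of this design
report both and the chain between them is exactly the mean-difference
filter.

### Deletion allele frequencies

Counting uses integer-rounded CN. On autosomes and the female X each
individual contributes 2 alleles (CN 0 → 2 deletion alleles, CN 1 → 1); on
the male X, 1 allele (CN 0 → 1). Individuals with integer CN ≥ 3 contribute
all their alleles as non-deletion: their allelic configuration (e.g. 1:2 vs
0:3) cannot be resolved from total CN, so the estimate is an explicit
*lower bound* on the deletion allele frequency. Under Hardy–Weinberg with
no amplified alleles the estimator is unbiased for the allele frequency,
which the test suite verifies by simulation.

### Ordination

Samples are embedded by Kruskal nonmetric MDS (stress-1, monotone
regression; `vegan::monoMDS` as the optimizer) on Euclidean distances over
per-gene z-scored copy numbers (divisor-*n* standard deviation;
zero-variance genes are dropped with a warning since they carry no
information and break the z-score). "Standardized" could also mean other
scalings; the z-score is the assumption here and `standardize_matrix()` is
the single place it lives. Nine starts are used — one classical-scaling
configuration plus eight random ones — and the lowest stress wins; all
randomness flows from one seed, so coordinates are reproducible.

One boundary case required a decision: configurations whose dissimilarities
are *all equal* (e.g. four mutually equidistant points). Under Kruskal's
primary treatment of ties, tied dissimilarities impose no constraints and
such inputs embed with stress 0, which contradicts the geometric
expectation that a regular tetrahedron cannot live in the plane. `nmds()`
therefore defaults to secondary tie treatment (tied dissimilarities keep
tied fitted distances), which reports positive stress there and is
identical on tie-free input — which Euclidean distances over real-valued
copy numbers essentially always are. `ties = "primary"` restores Kruskal's
default.

## The permutation null

CNVR–gene overlap statistics confound with interval sizes: long genes are
hit by chance more often. The null preserves the observed CNVR *lengths*
and re-places each interval uniformly over all valid start positions in the
gap-free genome (chromosome chosen proportionally to its number of valid
starts), independently, allowing placed intervals to overlap each other.
Chromosome of origin and inter-interval spacing are not preserved — this is
the simplest defensible size-matched null, and restricting placement to the
source chromosome is a straightforward variant the API leaves room for.
The empirical p-value uses the plus-one correction
`(r + 1)/(n_perm + 1)`, so it is never 0 and is honest about resolution at
small `n_perm`. Only the upper (enrichment) tail is reported; depletion is
obtained by negating the statistic.

## The synthetic-data generator

`sim_config()` describes a stated world, chosen once:

* **Design**: four populations of 8/8/8/3 with the 3-sample population
  containing the study's two females; 25 males total. Three synthetic
  25-Mb autosomes plus an X stand in for a full genome — the analyses are
  per-interval and per-gene, so genome size only scales runtime.
* **Annotation**: ~2000 transcription units with log-normal lengths
  (median 8 kb), ~50 SD blocks > 10 kb, two 50-kb assembly gaps per
  chromosome.
* **SD-associated CNVRs** (40): carrier frequency Beta(0.6, 0.6) —
  U-shaped, so some regions are near-fixed and some rare, matching the
  observed presence spectra of SD-overlapping CNVRs; per-carrier call
  lengths log-normal with median 10.7 kb; copy numbers a
  duplication-skewed mixture with mean ≈ 1.27 haploid copies.
* **Background calls** (Poisson, 150 per sample): log-normal lengths with
  median 3.8 kb; deletion-biased copy numbers with mean ≈ 0.67 haploid
  copies. Because each call is placed independently per sample, most
  resulting CNVRs are singletons — the observed behaviour of non-SD CNVs.
* **Planted truth**: 30 divergent genes (one population's mean shifted by
  +3 diploid copies, within-population SD 0.5), 40 genes with segregating
  whole-gene deletions (Hardy–Weinberg, per-population allele frequency
  uniform on [0.05, 0.6]; one allele drawn on the male X), 8 high-copy
  genes (per-population means uniform on [10, 40]). Planted calls span
  their gene with 0–200 bp of breakpoint jitter per side, exercising the
  containment boundary; genes are laid out so jittered calls of adjacent
  planted genes can never collide. Gaussian genotyping noise (SD 0.2
  diploid copies, truncated at 0 and kept on the correct side of the
  baseline) is applied to every emitted call.

Planted genic features are deliberately placed away from SD neighbourhoods
so the two planted signal classes cannot collide in one CNVR. A side
effect: the high-copy amplifications inflate the *non-SD* partition's mean
copy number, so the SD-vs-non-SD comparison in this synthetic world
reliably reproduces the *length* ordering (asserted in tests) but not
necessarily a copy-number ordering.

What the generator does **not** emulate: read-level noise and coverage
dependence of call quality (call boundaries are exact up to the planted
jitter), linkage between loci, relatedness within populations, mutation-
rate heterogeneity along the genome, gene clusters/tandem arrays, and any
sequence content. A green end-to-end test therefore establishes that the
analysis chain recovers the statistical structure it claims to measure —
not that a particular caller's biases are handled.

Same config and seed give byte-identical output files; per-sample call
files, annotation, and a truth table are emitted in the package's TSV
dialects.

## Numerical and degenerate-input conventions

* Rounding to integer CN is half-up (`floor(x + 0.5)`): 1.5 → 2.
* ANOVA with `MSE = 0, MSB > 0` reports `F = Inf, p = 0`; with
  `MSE = MSB = 0` the test is undefined (`NA`). `tukey_hsd()` refuses
  `MSE = 0` outright; the scan handles that limit itself (see above).
* KS p-values use the asymptotic two-sample distribution (via
  `stats::ks.test(exact = FALSE)`); with heavily tied data the p-value is
  approximate, and only the D statistic is asserted in tests.
* `bh_fdr()` delegates to `stats::p.adjust(method = "BH")` and is tested
  against the explicit step-up recursion.
* Empty inputs return empty results where that is well-defined (empty call
  set → zero CNVRs) and raise errors where it is not (empty sample in a KS
  test, < 2 samples per population in `vst`).

## Known limitations

* `v_st` has no sampling-variance correction; with n = 3 its per-gene
  values are noisy and the per-pair *means* are the more stable summary.
* The deletion-frequency lower bound ignores the possibility of deletion
  alleles hiding behind amplified homologues (by construction).
* The permutation null randomizes CNVRs, not individual calls; enrichment
  conclusions are about loci, not call counts.
* The CLI reruns are byte-identical only on the same platform/R version;
  floating-point formatting is fixed to full precision but numerical
  libraries may differ across builds.
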