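---
title: "Methods: CNV discovery, genotyping and population differentiation in canids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV discovery, genotyping and population differentiation in canids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canidcnv)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the assumptions behind them, the tunable
parameters with their defaults and rationale, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one reading was defensible.

## The measurement model

An aCGH chip reports, per probe, the log2 ratio of test-sample DNA to
reference-sample DNA. Under ideal hybridization a diploid test segment
(copy 2) gives log2(2/2) = 0, a one-copy loss gives log2(1/2) = −1, a
single-copy gain log2(3/2) ≈ 0.585, a two-copy gain log2(4/2) = 1.
Homozygous deletions have no finite log2; the package clamps their
expected signal at −3, far below every calling threshold while keeping
the arithmetic finite. All calls are *relative to the reference animal*:
a "loss" may be an ancestral deletion or a reference-specific
duplication, which is why polarization against gray wolves is a separate
step.

Probe noise is modelled as homoscedastic Gaussian (default SD 0.15 log2
units). Real arrays add dye bias, GC waves and spatial artifacts; those
are deliberately out of scope (see *Limitations*).

## Stage 1 — discovery

**HMM segmenter.** A fixed-architecture 3-state Gaussian HMM: state means
−0.6 / 0 / +0.45, a shared emission SD estimated from the track's median
absolute deviation (robust to the CNV probes themselves), self-transition
0.999. Means are intentionally conservative magnitudes: −0.6 sits between
the heterozygous-loss signal (−1) and 0, +0.45 below the heterozygous
gain (0.585), so both heterozygous and homozygous events decode to the
correct side. Forward–backward posteriors supply the per-segment support
(the mean posterior of the called state over the segment's probes), and
maximal non-normal runs of the Viterbi path become candidate segments.
Segments are kept when the average posterior exceeds 0.60 with ≥ 50
probes or 0.75 with 30–49 probes; shorter segments are discarded.

**Second caller.** An independent, deliberately simple method: per
chromosome, every maximal run of at least 30 consecutive probes all
beyond the chromosome median ± *k* robust SDs (MAD) on the same side is a
segment. We set *k* = 1. The choice is driven by run-length arithmetic:
the null probability that 30 consecutive Gaussian probes all exceed 1 SD
on the same side is Φ(−1)³⁰ ≈ 10⁻²⁴, so specificity is effectively
perfect for any *k* ≥ 1, while sensitivity collapses quickly as *k*
grows — at *k* = 2 a single-copy gain (0.585, ≈ 3.9 SD at noise 0.15)
has per-probe exceedance ≈ 0.97 and a 50-probe clean run survives with
probability only ≈ 0.23. With *k* = 1 the same gain passes probe-wise
with ≈ 0.998 and long runs survive reliably. The minimum run length, not
the threshold, carries the specificity.

**Combination.** The two callers are intersected: an HMM segment survives
iff ≥ 50% of its length is covered by same-state segments of the second
caller, and the surviving coordinates are the HMM's. Intersection (rather
than union) realizes a conservative discovery stage; the 50% coverage
threshold makes the rule robust to the second caller's run
fragmentation.

**Merging.** Within a sample, consecutive same-state segments join when
less than 3 kb apart or when more than 80% of the open interval strictly
between them is covered by repeats or assembly gaps (repeat-rich gaps are
not tiled with informative probes, so a CNV interrupted by them is
plausibly one event). The rule is closed transitively and is idempotent.
Across samples, overlapping (≥ 1 bp) segments are merged by single
linkage, *ignoring state*: a gain in one sample may overlap a loss in
another, and every sample is re-genotyped at every region afterwards, so
cross-state unions lose no information.

## Stage 2 — genotyping

Each sample's call at each region compares the mean log2 ratio over the
region's probes with the sample's chip-wide median ± 1.5 × SD (all probe
values of that chip). Ties exactly at a bound are non-equal calls, which
keeps the rule deterministic. The chip-wide anchoring assumes CNV-state
probes are a small minority of the chip, so that the SD reflects noise;
the synthetic array design preserves this property (below). Gains remain
intrinsically harder than losses — the heterozygous gain signal (0.585)
is closer to the threshold than the heterozygous loss (−1) — reproducing
the well-known loss/gain asymmetry of aCGH genotyping.

Sharing classes: *dog-specific* regions have a non-equal call in at least
one dog (the dingo counts as a dog throughout) and none in any wild
canid (gray wolves and the outgroup species); *wild-specific* is
symmetric; *shared* requires both; *monomorphic* neither. Polarization is
narrower by design: a *post-domestication duplication* (deletion) is a
gain (loss) present in ≥ 1 dog and absent from all gray wolves — the
outgroup species are not consulted, and one region can carry both flags.

## Population genetics

**EM allele frequencies.** Genotypes are collapsed to three categories
(loss / equal / gain). Under Hardy–Weinberg with per-haplotype copies
L = 0, N = 1, G = 2, the diploid phenotype map is copy < 2 → loss
(LL, LN), copy = 2 → equal (NN and the GL heterozygote), copy > 2 → gain
(NG, GG), giving class probabilities P(loss) = r² + 2pr,
P(equal) = p² + 2qr, P(gain) = q² + 2pq. The allele-counting EM maximizes
the multinomial likelihood, stopping when the log-likelihood improves by
less than 1e−10 or after 1,000 iterations.

Two numerical facts shape the implementation:

* *The uniform point is an exact fixed point of the EM map* (complete
  label symmetry), and for symmetric counts it is a saddle, so EM must
  not start there. We start from smoothed category proportions
  ((n_k + 0.5)/(n + 1.5)).
* *The likelihood can be bimodal and is not always identified.* The
  "equal" class can be explained by NN homozygotes or by GL
  heterozygotes; some count vectors have two local optima, and interior
  optima can lie on a ridge of distinct (p, q, r) with identical class
  probabilities. EM is therefore run from four deterministic starts
  (category proportions plus three corner-biased points) and the best
  log-likelihood kept; the test suite compares EM against a grid-search
  oracle on the identifiable scale (class probabilities and
  log-likelihood). Biallelic loci — a normal allele plus a single loss
  *or* gain allele, the realistic case for these data — are fully
  identified. On the simplex boundary (fixation) EM converges
  harmonically, so at the iteration cap fixed loci report frequencies
  within ~10⁻³ of 0 or 1 rather than exactly.

**Heterozygosity.** He = 1 − (p² + q² + r²), maximal at 2/3. Both
EM-based He (default for group summaries) and direct category-proportion
He are available; the wolf-subsampling comparison uses direct
frequencies, since it recomputes He on 5-wolf subsets where EM adds
variance without information. The comparison draws 1,000 random wolf
subsets of the dog group's size, averages He over polymorphic regions
(≥ 1 non-equal call among dogs and gray wolves), and reports
p = (#{subset mean ≤ dog mean} + 1)/(n + 1); the +1 convention never
returns 0 and is used by every empirical p-value in the package.

**VST.** For each region, VST = (VT − VS)/VT on per-sample region mean
log2 ratios (not on the 3-category calls — the statistic is designed for
the continuous signal): VT is the unbiased (n − 1) variance over dogs
plus gray wolves, VS the population-size-weighted mean of the two
within-group (n − 1) variances, and VT = 0 yields VST = 0 by convention.
With small groups VST can be slightly negative (VS > VT); ranking is
descending with (chromosome, start) tie-breaks for determinism.

## Breakpoint architecture

Breakpoints are 400 bp windows centered on region boundaries — the width
absorbs array-resolution uncertainty and equals the smallest CNV the
design can detect. GC peaks are ≥ 500 bp runs whose GC exceeds 1.5 × the
GC of a 10 kb background window centered on them; the background
*includes* the peak span ("centered in" implies containment), the scan
step is 100 bp (a compromise between resolution and cost; the criterion
is re-checked on merged peaks before reporting), N bases never enter GC
denominators, and windows more than half N are dropped.

The homology statistic is the longest common substring of the two
breakpoint-window sequences (N matches nothing); the implementation is a
binary search over candidate lengths with substring-set intersection and
is verified against the quadratic dynamic-programming oracle. Null
distributions for homology, GC-peak proximity and repeat enrichment all
come from the same redistribution scheme: each breakpoint pair is
re-placed uniformly on its own chromosome with the two breakpoints kept
at exactly their original distance; redistributed pairs may overlap one
another. That simplification is harmless at realistic density (hundreds
of CNVs on chromosomes of tens of megabases) but biases null overlap
counts low when pairs are crowded onto a short chromosome — calibration
tests therefore use sparse layouts. Homology significance uses a
two-sample Wilcoxon rank-sum test between real and redistributed
per-pair values (exact when the pooled sample is under 30 and untied,
tie-corrected normal approximation otherwise); enrichment tests report
observed/expected ratios against the null mean with one-sided
(b + 1)/(n + 1) p-values; the gene-overlap test is two-sided, counting
null sets at least as far from the null mean as the observation, since
both enrichment and depletion are of interest.

The gene-overlap null preserves the array's footprint: each simulated set
places, per target region, a same-length window uniformly inside a
uniformly chosen universe region that can hold it. Drawing from the whole
genome instead would confound the question "are these regions gene-rich
*for array regions*?" with the array's own design bias.

## The synthetic-data generator

The generator's defaults are the study conditions the pipeline is tested
under:

* 23 samples: 4 purebred dogs + 1 dingo (dog group; the Boxer is the
  hybridization reference, so its own track is self-self noise and its
  truth genotypes are forced normal), 15 gray wolves, 3 outgroup canids.
* A 3 Mb genome (2 chromosomes) at 41% background GC with implanted GC
  peaks (half centered on CNV locus boundaries, emulating the observed
  association of GC peaks with breakpoints), N-run assembly gaps,
  repeats (L1 with five age-class labels from lineage-specific to
  ancient, SINE, simple repeats; a fraction of L1/simple elements placed
  near breakpoints) and gene annotations.
* 60 CNV loci of 2.5–12 kb with a scenario mix matching the study's
  composition: 55% of array loci monomorphic in the panel, 20% shared
  polymorphisms, 10% dog-specific (half of those highly differentiated:
  dog gain allele at frequency 0.9, absent in wolves), 15%
  wolf-specific; ordinary polymorphic loci use variant allele frequency
  0.3. Truth genotypes are two independent Hardy–Weinberg draws per
  sample per locus.
* Array design: probe spacing 50 bp for tiled regions under 100 kb,
  150 bp to 300 kb, 1 kb beyond; 42 single-copy control regions
  (42 × 23 = 966 control genotype tests); each CNV locus tiled with
  10 kb of flank. The flank keeps CNV-state probes a small minority of
  the ~34,000-probe chip, as on the real array, where tiled regions
  (~58 kb on average) dwarf the CNVs they contain — without it the
  chip-wide SD used by the genotyper is inflated by the CNV probes
  themselves and heterozygous gains become uncallable, a desk-scale
  artifact rather than a property of the method.
* Homoscedastic Gaussian probe noise, SD 0.15.

Everything is a pure function of (configuration, seed); every stochastic
stage derives a sub-seed from the master seed and a stage label, so
stage outputs do not depend on how much randomness earlier stages
consumed.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: dye bias, GC waves and spatial artifacts;
probe-level dropout in repeats; breed pedigree and population structure
within groups; linkage between loci; ascertainment bias of an array
designed from dog discoveries (the real panel's dog/wolf He contrast is
shaped by that bias); and breakpoint homology — by default breakpoints
carry no implanted homology, so the pipeline's homology test on default
synthetic data is a true null, and the positive case is exercised by
implanting motifs explicitly.

## Problem sizes used by the tests

The test suite and acceptance script run at desk scale, chosen so the
full suite completes in minutes while every statistical property keeps
enough resolution to be meaningful: the default 3 Mb / 60-locus /
23-sample study for recovery and recall checks; 100-replicate parameter
recovery at 200 samples per replicate; calibration suites of 200
replicates × 200 resamples with landscapes redrawn per replicate (a
fixed landscape aligns the empirical-p atoms produced by discrete
overlap counts and no (b + 1)/(n + 1) p-value would look uniform);
homology oracle checks on 500 random sequence pairs up to 60 bp; and the
EM–grid comparison over every count vector with total ≤ 12 at grid step
0.001.

## Known limitations

* Three-category genotypes discard integer copy number; loci where
  samples segregate for both gains and losses are summarized coarsely,
  and the EM frequencies for such loci are not identified (only their
  class probabilities are).
* Gains near the 1.5 SD genotyping threshold are under-called — a real
  asymmetry of the assay that the pipeline reproduces rather than
  corrects.
* The second caller assumes a unimodal null per chromosome; a chromosome
  that is mostly CNV would shift the median and mask calls. The robust
  (MAD) scale limits but does not eliminate this.
* Redistribution nulls allow pair collisions; at high CNV density on
  short chromosomes they under-estimate expected overlap.
* Breakpoint placement is probe-limited: coordinates are probe positions,
  so sub-probe-spacing precision is not claimed, and the 400 bp windows
  absorb that uncertainty rather than remove it.
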