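---
title: "Classifying promoter occupancy from ChIP-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying promoter occupancy from ChIP-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promclass)
```

`promclass` separates the promoters bound by a chromatin factor into a
strong, initiation-site-peaked class (group I) and a weaker,
downstream-peaked class (group II), and characterises the two classes
against standard regulatory annotation. This vignette explains the
model behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
choices made where the problem was genuinely open.

## Coordinates and promoters

All public interfaces use BED conventions: 0-based, half-open
intervals. The TSS of a plus-strand transcript is `tx_start`; for a
minus-strand transcript it is `tx_end` (the exclusive end), so the
first transcribed base of a minus gene sits at `tx_end - 1`. All
strand-oriented offsets are measured from that first transcribed base,
which makes every profile and matrix exactly invariant under mirroring
the genome and flipping strands — a property the test suite asserts
bit-for-bit.

Transcripts sharing a (chromosome, strand, TSS) triple are alternative
isoforms of the same promoter and are merged: their ids are
concatenated and the merged promoter takes the *maximum* expression of
its contributors. Mean or sum would dilute or double-count an active
gene whose silent isoform shares the TSS; max answers the question the
promoter-level analysis asks ("how active is this start site?").

Two windows appear throughout and are deliberately distinct:

* the **promoter window**, −1,000/+1,000 bp around the TSS — used for
  all binary annotation (enhancer exclusion, TATA/ETS flags, TF event
  counts) and for all binding-*strength* measurements;
* the **heatmap window**, −1,500/+1,500 bp in 50 bp bins — used for
  profile *shape* (classification, average profiles). 50 bp resolves
  the +60 bp pausing peak while keeping a 2,000-promoter matrix at
  60 columns.

Measuring strength on the promoter window rather than the full heatmap
flank matters: signal bleeding in from a promoter 1–1.5 kb away would
otherwise be mistaken for binding.

## Signal matrices

Each mapped read contributes one tag at its 5' end shifted 100 bp
towards 3' — half the 200 bp fragment length, the standard point
reduction for single-end ChIP-seq. Tags are binned per promoter,
strand-oriented (bin 1 is always the most upstream bin), and
normalised to tags per million mapped reads; the raw count matrix is
retained so that binned rows sum exactly to the windowed tag counts
(an invariant the tests check). Counting is unstranded: a tag
annotates a promoter regardless of the strand it mapped to.

## Bound promoters and the group I/II split

A promoter is *bound* when its promoter-window signal strictly exceeds
2× the matched IgG control at the same promoter. The 2-fold default is
a conservative reading of "weakly bound but enriched"; it is
configurable, and without a control the expected uniform background
`1e6 × window / genome_size` substitutes with a warning.

Classification runs Euclidean k-means (k = 2, 10 random restarts under
a fixed seed) on the bound rows of the heatmap matrix after scaling
each row by its maximum. Row scaling makes peak *position* rather than
amplitude drive the split — the two classes differ in shape (upstream
peak versus +60 bp peak with an upstream shoulder), not only in
strength. Amplitude re-enters through the labelling rule: whichever
cluster has the higher mean promoter-window signal is group I, always.
This makes the labels invariant to cluster numbering and to
relabelling, and it encodes the definition of group I (the strong
class) rather than leaving it to chance. k is fixed at 2 by default
because the phenomenon being modelled is a two-class split with no
intermediate state; k is configurable, but no third class is modelled.

Degenerate input (fewer distinct scaled rows than k) returns all
promoters in group I flagged `degenerate` with zero within-cluster SS,
rather than crashing — identical rows carry no shape information to
split on.

The headline strength statistic is the fold ratio
`mean(signal_I) / mean(signal_II)` on the promoter window.

## The Poisson peak caller

The caller slides 300 bp windows in 150 bp steps. A window with `k`
tags is significant when `P(X ≥ k; λ_local) < p_cutoff`, with
`λ_local = max(λ_genome, λ_5kb, λ_10kb)` scaled to the window — the
local-background idea of model-based callers, without their fragment
model: the shift is a fixed parameter here. Overlapping significant
windows merge into one peak that reports the merged interval's tag
count and the minimum window p-value. The caller is calibrated (on
uniform background the false-positive window rate stays below the
cutoff, with a wide margin because `λ_local` is conservative) and
monotone: raising the cutoff never shrinks any peak, and adding reads
inside a peak never removes it. It makes no claim of reproducing any
specific caller's coordinates bit-for-bit; q-values and paired
controls are out of scope.

## Enrichment scores and statistics

For a factor with per-promoter tag counts, `X = mean(group I) /
mean(all promoters)` and `Y = mean(group II) / mean(all promoters)`.
The factor is called enriched at group I when `X ≥ 1.1 Y` — "at least
10% more" read on the ratio scale, which keeps the call invariant to
rescaling all counts (also asserted by tests). Counts are taken on the
promoter window.

The expression-quintile analysis excludes group I, orders the
remaining promoters by expression (ties broken by stable input order),
cuts them into five contiguous classes whose sizes differ by at most
one, and reports the Pearson correlation between the five quintile
means of two factors — the quantitative form of "occupancy tracks
polymerase across expression classes".

Overlap enrichment uses the hypergeometric upper tail
`P(X ≥ k)` (two-sided doubling available behind an argument);
group comparisons use Welch's unequal-variance t-test, the safer
reading of "unpaired t-test" when one group is an order of magnitude
smaller than the other (tens versus thousands of promoters). Box
summaries report the 5/25/50/75/95% quantiles (type-7 interpolation).

## The knockdown DE filter

A gene is consistently changed when it passes the volcano cutoff at
*both* timepoints: `|log2 FC| ≥ log2(2)` (fold inclusive) and
`p < 0.05` (strict). The boundary conventions are explicit because a
gene at exactly 2-fold should count as "two-fold changed" while
`p = 0.05` should not count as `< 0.05`. No multiple-testing
correction is applied by default — the filter consumes the raw
p-values its upstream produced — but `adjust = "BH"` is available.
The filter is monotone in both cutoffs, which the tests verify on
random cutoff pairs. The bound-gene shift test compares mean log2
fold-change (averaged over the two timepoints) of bound versus unbound
genes by Welch's test.

## The synthetic-data generator

The generator emits a miniature genome whose statistical structure is
the one the analysis assumes, with complete ground truth. Defaults
encode the study conditions: 2 chromosomes × 5 Mb, 2,000
non-overlapping genes, 1 M reads per factor; 13% of promoters bound,
7.5% of the bound set in group I; an 8-fold group I : group II
amplitude ratio; group I peaking 60 bp upstream of the TSS, group II
60 bp downstream with a 40% shoulder at −150 bp; 112 versus 75 mean TF
binding events per group I/II promoter (50 unbound); and a DE table of
20,000 genes with 150 consistently up- and 58 consistently
downregulated genes planted. At these sizes every stage runs in
seconds, and the test suite sweeps ten seeds in about a minute.

Mechanics and the reasoning behind them:

* **Binding profiles** are Gaussian positional kernels (σ = 75 bp)
  around the class-dependent offset; the shoulder is a second Gaussian
  at −150 bp with 40% weight. The source data show shapes, not a
  functional form; a Gaussian mixture is the simplest shape with the
  right peaks.
* **Expression** is log-normal (meanlog 2, sdlog 1 — a typical
  microarray-like dynamic range). Bound promoters are sampled with
  probability ∝ expression^0.5 (bound promoters are more active than
  average), and group I is the top-expression tail of the bound set.
* **Amplitude–expression coupling.** Pol II amplitude is proportional
  to expression at every promoter. The main factor couples
  sub-linearly (exponent 0.5) within each class, normalised so the
  class-mean amplitude is exactly the configured fold. Sub-linear
  coupling keeps the weakest group II promoters separable from
  background at the 2-fold selection threshold while preserving the
  monotone occupancy–expression relationship the quintile analysis
  measures; with linear coupling the low-expression tail of group II
  would fall below any fixed enrichment threshold and the
  bound/unbound distinction would stop being recoverable at desk
  scale.
* **TSS spacing.** Genes live in disjoint slots with every TSS at
  least 1,250 bp from its slot boundaries, so promoter windows never
  capture a neighbour's signal. Real genomes do contain closely spaced
  and divergent promoter pairs; they are deliberately not modelled
  (see limitations).
* **Null DE fold-changes** are truncated to (−0.9, 0.9), so no null
  gene can cross the 2-fold cutoff and the planted sets are the exact
  ground truth. The truncation only removes events that would
  otherwise occur with probability ~10⁻⁴ per gene per timepoint.
* **Annotation tracks** carry class-dependent statistics: Poisson TF
  event counts, Bernoulli CpG/TATA/ETS flags (CpG enriched and TATA
  depleted at bound promoters), G4 sites split between promoters,
  enhancers and background, and H3K4me1/H3K27ac pairs at true enhancer
  loci plus single-mark and promoter-overlapping decoys that the
  enhancer definition must reject.
* **Determinism.** Every stage derives its RNG stream from the
  configured seed and restores the caller's RNG state; identical seeds
  give byte-identical datasets, which the tests assert.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: sequence content (reads are
intervals; no mappability or GC bias), duplicate reads, copy-number
variation, closely spaced or divergent promoters, chromatin-state
correlation between neighbouring genes, and any intermediate binding
class between groups I and II. Recovery accuracy of ~1.0 on synthetic
data is a correctness check of the pipeline, not an estimate of
accuracy on a real genome, where the class boundary is fuzzier.

## Numerical choices and degenerate inputs

* Half-open interval arithmetic throughout; adjacent intervals do not
  overlap.
* Enhancers are the *intersections* of overlapping H3K4me1/H3K27ac
  pairs (merged, promoter-free). Intersection versus union was an open
  call; intersection is the stricter choice and makes the enhancer set
  invariant to how peak callers pad their peaks.
* Peak-category precedence is fixed (promoter first, intergenic last)
  so categories always partition a peak set; fractions sum to exactly 1.
* Quantile type 7 (R's default interpolation) for box summaries;
  quintile ties broken by stable input order so the partition is
  reproducible.
* Empty inputs error early with messages naming the offending
  argument; malformed gene records are dropped with a warning rather
  than aborting a whole annotation file; reads on chromosomes absent
  from the promoter set are skipped and counted in a message.

## Known limitations

The k-means split assumes exactly two shape classes; a genome with a
continuum of profiles will still be forced into two groups. The peak
caller's `λ_local` uses the treatment itself, so very broad enriched
domains inflate their own background and can suppress calls inside
them. The bound/unbound threshold is a hard 2-fold cutoff, not a
posterior probability. And the acceptance-level recovery numbers are
properties of the generator's idealised genome, not of any organism's.
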