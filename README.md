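# promclass

Classification and characterisation of ChIP-seq-bound gene promoters.

Some chromatin factors — DNA-repair demethylases among them — occupy
thousands of promoters at two visibly different intensities: a small
"hyperactive" class with a strong occupancy peak just upstream of the
transcription start site (TSS), and a much larger class with weaker
binding that peaks ~60 bp downstream, where RNA polymerase II pauses.
`promclass` implements the genomic analysis that separates and
characterises these classes, for analysts working from aligned ChIP-seq
reads (BED), a RefSeq-style gene table, and standard UCSC annotation
tracks.

## What it computes

* **TSS-anchored signal matrices.** Each read is reduced to its 5' end
  shifted 100 bp towards the fragment centre; tags are binned into
  50 bp bins over a strand-oriented ±1,500 bp window around every
  deduplicated TSS, normalised to tags per million mapped reads.
* **Promoter classes.** Promoters enriched ≥2-fold over a matched IgG
  control (on the −1,000/+1,000 promoter window) are clustered with
  Euclidean k-means (k = 2) on max-scaled profile rows. The cluster
  with the higher mean promoter-window signal is always **group I**;
  the weaker is **group II**. The strength ratio is
  `mean(signal_I) / mean(signal_II)`.
* **A Poisson peak caller.** 300 bp windows sliding by 150 bp, tested
  against `λ_local = max(λ_genome, λ_5kb, λ_10kb)` with the Poisson
  upper tail `P(X ≥ k; λ_local)`; overlapping significant windows merge
  into peaks. Deliberately simpler than MACS (no model building), but
  calibrated: on pure background the false-positive window rate stays
  below the p-value cutoff.
* **Feature annotation.** Enhancers = promoter-free intersections of
  H3K4me1/H3K27ac peak pairs; G4 sites filtered to lie outside
  promoters and enhancers; TATA (conserved TBP site), ETS and CpG
  flags; TF binding events = overlapping clustered-TFBS records per
  promoter; peak categories with promoter > 5'UTR > 3'UTR > exon >
  intron > intergenic precedence.
* **Statistics.** Per-factor enrichment scores
  `X = mean(group I)/mean(all)`, `Y = mean(group II)/mean(all)` with an
  `enriched_I` call when `X ≥ 1.1·Y`; expression-quintile occupancy
  correlation (Pearson r over quintile means, group I excluded);
  hypergeometric overlap tests; Welch t-tests; 5/25/50/75/95% box
  summaries.
* **Knockdown DE filter.** Genes with ≥2-fold change and p < 0.05 at
  *both* of two timepoints, split into up/down sets, plus a Welch test
  for an expression shift at factor-bound genes.
* **A synthetic-data generator** producing a miniature genome (2 × 5 Mb,
  2,000 genes, 1 M reads per factor) with full ground truth: class
  labels, configured amplitude folds, planted DE sets. Every stage of
  the pipeline is testable against it without downloads.

## Worked example

```r
library(promclass)

ds  <- simulate_dataset(sim_config(seed = 1))   # miniature genome + truth
res <- run_pipeline(ds, seed = 1)

print(res$matrix)
#> SignalMatrix: 2000 promoters x 60 bins of 50 bp; 1000000 mapped reads

table(res$assignment$group)
#>   I  II
#>  20 240

round(res$fold_ratio, 2)
#> [1] 7.69          # group I binds ~8-fold stronger than group II

print(res$enrichment, digits = 3)
#>   factor_name x_score y_score         call
#> 1        TAF1   1.512   0.991   enriched_I
#> 2    H3K122ac   1.419   0.999   enriched_I
#> 3        CHD7   1.280   1.002   enriched_I
#> 4         TBP   1.014   0.995 not_enriched
#> 5    H3K27me3   0.607   1.007 not_enriched

round(res$quintile_r, 3)
#> [1] 0.959         # factor occupancy tracks Pol II across quintiles

lengths(res$de)
#>   up down
#>  150   58          # consistently changed genes at both timepoints
```

The 260 bound promoters split into a 20-promoter strong class and a
240-promoter weak class; the enrichment table recovers the configured
per-class factor folds (1.5, 1.4, 1.3 for the three planted enriched
factors) and calls them enriched at group I, while the unchanged and
depleted factors are not called.

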