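# acetylscape

Statistical pipeline for studying how mitochondrial dysfunction rewires
promoter histone acetylation and, through it, gene expression. Progressive
mitochondrial DNA depletion drains the acetyl-CoA pool that histone
acetyltransferases depend on; promoter H3K9ac/H3K27ac marks decay over the
depletion time course, expression of the marked genes follows, and a
cell-permeable TCA substrate (dimethyl-α-ketoglutarate) partially reverses
both. `acetylscape` implements the quantitative core of such a study as a
tested R package, exercised end to end on a synthetic-data generator with
known ground truth.

## What it computes

* **Input-normalized narrow peak calling.** Per bin, a one-sided Poisson
  test of ChIP counts against λ = max(genome-wide mean, local ±5 kb mean)
  of the background-scaled input, aggregated over ~250 bp windows,
  Benjamini–Hochberg controlled genome-wide (q ≤ 0.01), adjacent
  significant bins merged.
* **Reproducible-peak consensus.** An irreproducible-discovery-style filter:
  matched replicate peaks are kept when the posterior probability of the
  rank-inconsistent mixture component is ≤ 1%, then merged into consensus
  tags.
* **AUC promoter score.** Per tag,
  `AUC = (ChIP RPM − input RPM) / length`, the length-adjusted net
  enrichment (RPM/bp).
* **TSS metaprofiles** (±2 kb, strand-oriented) and ChIP QC (FRiP,
  between-replicate log-RPKM correlation over 10-kb TSS windows).
* **Temporal trajectories.** log₂ enrichment relative to the reference
  time, tested per time point with an exact conditional binomial test on
  tag counts; Ward clustering separates monotone-loss (cluster A) from
  transient-gain (cluster B) patterns.
* **Differential expression and rescue.** Row-wise ANOVA (optional
  empirical-Bayes variance moderation), TOST equivalence testing, and
  classification of treatment-sensitive genes into
  full / partial / exacerbated / none rescue classes.
* **The headline association.** For a 2×2 table of DEG status × promoter
  peak change over an expressed-gene universe:
  `OR = ad/bc`, Woolf logit CI, two-sided Fisher exact p (point-probability
  method).
* **Consensus-rule SNP calling.** samtools-mpileup text → per-column base
  counts → a variant wherever one alternate base exceeds 80% of the reads
  (strictly), → VCFv4.2 → between-sample set comparison.

## Worked example

```r
library(acetylscape)

# a synthetic depletion study: 1,500 genes, planted odds ratio 2.4
cfg <- synth_config(n_genes = 1500, planted_or = 2.4, seed = 42)
res <- synthetic_association(cfg)
res$result
#> OR = 2.292 (95% CI 1.829-2.873), p = 6.16e-13 [fisher]
res$table
#>         changed unchanged
#> DEG         230       226
#> non-DEG     321       723

# temporal pattern classes of the significantly changed tags
cl <- cluster_trajectories(res$chip$trajectories, k = 2)
table(cl$label)
#>   A   B
#> 517  59

# treatment rescue of the sensitive genes
em <- make_expression(cfg, res$truth)
rescue <- classify_sensitivity_and_rescue(em, adjust = "BH",
                                          moderation = "eb")
table(rescue$rescue_class[rescue$sensitive])
#> exacerbated        full     partial
#>          27          24          32
```

The recovered odds ratio (2.29, CI covering the planted 2.4) says that
genes with a significant promoter peak change are about 2.3× more likely to
be differentially expressed than genes without one. Most changed tags decay
monotonically (cluster A); a minority show the transient gene-body gain
(cluster B). Of the treatment-sensitive genes, about 70% (full + partial)
have their expression change rescued, matching the planted rescue fraction.

`run_pipeline(cfg, outdir)` runs the same analysis through the on-disk
formats (bedGraph tracks, TSV tables, mpileup, VCF) and writes a
`manifest.json` with every threshold, the seed and file checksums; reruns
with the same config are byte-identical.

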