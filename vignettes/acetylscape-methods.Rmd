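---
title: "Methods: promoter acetylation dynamics coupled to expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter acetylation dynamics coupled to expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mitochondrial output feeds the nuclear epigenome: acetyl-CoA produced in the
mitochondria is the substrate of histone acetyltransferases, so progressive
mitochondrial DNA depletion starves promoters of activating acetylation marks
(H3K9ac, H3K27ac) and remodels transcription. `acetylscape` implements the
desk-scale statistical machinery used to study this coupling: quantify
promoter acetylation from input-normalized ChIP-seq over a depletion time
course, classify how peaks move over time, ask whether peak change is
enriched among differentially expressed genes (the headline odds ratio),
classify which expression changes a metabolic treatment rescues, and call
SNPs in acetyltransferase genes with a bespoke consensus rule. A synthetic
data generator plants all of this structure with known truth so that every
stage can be validated end to end.

# Coverage model and peak calling

Tags are held in fixed-width bins (default 50 bp; the analysis consumes
binned densities, not alignments). `call_peaks()` tests each bin's ChIP
count against a Poisson background whose mean is the larger of the
genome-wide mean and a centered +/-5 kb running mean of the scaled input
track. Two numerical choices matter:

* **Input scaling.** The input is scaled to the ChIP *background* level via
  the ratio of per-bin medians, not the total-library ratio. A ChIP library
  with a large fraction of reads in peaks would otherwise inflate the
  background estimate roughly (1 - FRiP)^-1 -fold and suppress weak true
  peaks. When a median is zero the scale falls back to the library ratio.
* **Window aggregation.** Counts are summed over a sliding window of
  `2*smooth_bins + 1` bins (default 5 bins = 250 bp, the scale of a
  sequenced fragment) before testing. Window sums of Poisson counts are
  Poisson, so the tail test stays exact while peaks become wide enough to
  overlap reliably between replicates.

P-values are Benjamini-Hochberg adjusted genome-wide; bins with
`q <= q_threshold` (default 0.01) and counts strictly above expectation are
merged into peaks when adjacent. The summit is the maximum-count bin.

# Replicate reproducibility

`reproducible_peaks()` matches peaks 1:1 between two replicates (largest
overlap, then leftmost) and scores rank consistency of `-log10 p` (ties
broken by enrichment, since strong peaks underflow to p = 0). The absolute
difference `d` of normalized ranks is modelled as a two-component mixture:
an irreproducible component with the density of `|U - V|` for independent
uniform ranks, `2(1 - d)`, and a reproducible component modelled as a
truncated exponential concentrated at zero. The mixture is fitted by EM and
each pair's irreproducibility is its posterior probability of the
independent component; pairs at or below the threshold (default 1%) merge
into consensus tags. This keeps the filter's contract — identical replicate
lists all pass at any threshold, unrelated score orderings collapse the
passing fraction toward zero — without reproducing a full copula mixture,
which the surrounding analysis only ever uses as a 1% filter. Per-time
consensus sets are unioned (`consensus_tags()`) into one reference frame.

# The AUC score and trajectories

For a tag interval, `auc_score()` is RPM-adjusted ChIP minus RPM-adjusted
input, divided by the interval length (units: RPM/bp; negative when ChIP
falls below background). Partial bins contribute proportionally, making the
score additive over sub-intervals.

`analyze_chip()` scores every reference tag in every library. For the
*temporal* comparison the ChIP libraries are normalized by their coverage
outside the consensus tags rather than their total size: when a large share
of the genome-wide signal decays, total-count RPM would mechanically inflate
unchanged tags into apparent transient gains. (The plain `auc_score()`
definition is unchanged; this only affects the trajectory stage, and mirrors
background normalization as practiced in differential-binding analysis.)

`build_trajectories()` averages replicates, clamps scores at a positivity
floor (the 1st-percentile order statistic of positive scores) and takes
log2 fold against the reference time (default the first). Significance per
tag and time uses, by default, an exact conditional binomial test on summed
tag counts given the background-effective library sizes: with two ChIP
replicates per time point a replicate-level t-test has two degrees of
freedom and essentially no power, whereas conditioning two Poisson totals
on their sum gives a calibrated exact test. The replicate-score t-test
remains available (`test = "t"`). A tag is "changed" when any time point
has BH `q < alpha` *and* |log2 fold| >= `min_lfc` (default 0.4); the effect
floor keeps statistically significant but biologically negligible
fluctuations of strong peaks out of the changed set.

Ward-linkage clustering (`cluster_trajectories()`, Ward.D2 on Euclidean
distances, k = 2 by default) labels cluster centroids by shape: monotone
non-increasing with net loss is pattern **A** (progressive loss); an
interior maximum that returns toward baseline is pattern **B** (transient
gain, the signature of the displaced gene-body peaks); anything else is
`other`.

# Expression statistics

`call_degs()` is a row-wise one-way ANOVA (pooled-variance t-test for two
groups), flagged at `alpha` on raw p (`adjust = "none"`, the study's stated
rule) or on BH q. `moderation = "eb"` squeezes the within-group variances
with `limma::squeezeVar()`; with three replicates per condition this is the
standard way to buy back degrees of freedom, and the orchestration layer
uses it so that DEG misclassification does not attenuate the association
estimate.

`tost_equivalence()` is the Welch two-one-sided-tests procedure: the
equivalence p is the larger of the one-sided p-values against -delta and
+delta. Zero-variance inputs are defined: p = 0 inside the bounds, 1
outside.

`classify_sensitivity_and_rescue()` calls a DEG treatment-sensitive when
treated vs depleted is significant, then classifies by the movement
fraction `m = (fc_d - fc_t)/fc_d` (fc in log2, against control): `full`
when |fc_t| <= `full_band` (0.25), `exacerbated` when m < 0, `partial` when
m >= `partial_frac` (0.5) without overshooting (|fc_t| < |fc_d|), `none`
otherwise. The source study never quantifies "partially or fully rescued";
these two thresholds are explicit configuration, echoed in the result's
attributes, and the four labels partition the sensitive set by
construction.

# The association statistic

`build_table()` cross-tabulates DEG status against promoter peak change
over an *explicit* expressed-gene universe (the published universe is
numerically ambiguous, so it is always an input). A gene "has a peak
change" when at least one consensus tag assigned to it (interval-to-TSS
distance <= 2 kb, `assign_to_gene()`; equidistant ties to the smaller gene
id) is flagged changed. `odds_ratio_test()` computes OR = ad/bc with the
Haldane +0.5 correction iff a cell is zero, a Woolf logit 95% CI, and a
two-sided Fisher exact p by the point-probability method (the sum of
hypergeometric masses no greater than the observed one); a
continuity-corrected chi-squared alternative exists for very large tables.
`concordance()` reports sign agreement and Spearman correlation between
expression fold changes and enrichment deltas.

# The consensus-rule SNP caller

`read_pileup()` parses samtools mpileup text exactly: `^q` consumes two
characters, `$` one, `+n`/`-n` consume the run length and its digits,
`*` is a deleted-base placeholder, and forward/reverse case is pooled. A
declared-vs-parsed depth mismatch is an error naming the position.
`call_snps()` emits a variant when the single most frequent alternate base
exceeds the threshold fraction of the full declared depth — strictly
greater than 80% by default, so 80.0% is never called — at columns with
depth >= `min_depth` (default 4; the source protocol states none, and the
value is recorded in the VCF header). Indels obey the same rule
(`extract_indels()`); set comparison (`diff_snp_sets()`) keys on
(chrom, pos, alt) by default because position-only keying conflates
different substitutions, with a position-only mode for fidelity with
interval-based comparisons.

# What the generator emulates — and what it does not

`synth_config()` defaults encode the emulated design: four time points
(d0/d3/d6/d9), two ChIP and three expression replicates, ~30% DEGs, a
planted DEG-by-peak-change odds ratio of 2.4, ~18% of DEGs
treatment-sensitive with ~70% of those rescued, and >80%-fraction planted
variants. Peaks are triangles (closed-form area `h*hw`, giving exact AUC
oracles) whose per-gene strengths are lognormal (sdlog 0.5): real promoter
peaks span orders of magnitude, and without that spread peak-significance
ranks are ties plus noise and no rank-based reproducibility filter can
work. Pattern-B genes keep a decaying TSS peak and gain a displaced
gene-body peak with a rise-and-return trajectory. The marginal peak-change
rate among non-DEGs is a free parameter (`change_rate_nondeg`, default
0.3): the published counts do not pin it down, and the planted 2x2 table is
solved from it, `frac_deg`, and `planted_or`.

The generator does **not** emulate: read-level artifacts (mappability,
duplicates, GC bias), fragment-size geometry, overdispersion beyond
Poisson, correlated replicate effects, array preprocessing, or multi-gene
regulatory structure. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under the planted model, not that real
libraries meet its assumptions.

# Problem sizes and validation design

The validation suite runs the full pipeline at 5,000 genes for odds-ratio
recovery (20 replicate simulations; the Woolf CI covers the planted 2.4),
300 genes for pattern recovery (10 simulations), 10,000 null genes for DEG
type-I error, and 50,000-bin null tracks for peak error control — sizes at
which every Monte-Carlo band in the tests is computed from the binomial or
Poisson sampling noise of the quantity being checked. `scripts/acceptance.R`
re-runs the main computations from scratch at the same sizes.

# Known limitations

* The reproducibility filter's EM is a deliberately reduced two-group
  rank-consistency estimate; it shares the interface and threshold
  semantics of a full IDR analysis but not its copula model.
* The exact binomial trajectory test assumes Poisson tag counts; on real
  (overdispersed) libraries the t-test option or an explicit dispersion
  model would be more conservative.
* `assign_to_gene()` measures interval-to-TSS distance (a summit mode is a
  one-line change) and ignores transcript isoforms.
* The SNP caller has no base-quality model; it reimplements a counting
  rule, not a genotyper.
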