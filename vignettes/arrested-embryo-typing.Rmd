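---
title: "Typing developmentally arrested IVF embryos from single-embryo RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing developmentally arrested IVF embryos from single-embryo RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Roughly 60% of in vitro fertilized human embryos irreversibly arrest before
compaction, typically between the 2-cell and 8-cell stages. Single-embryo
RNA-seq places these arrested embryos on the normal developmental expression
axis and lets several independent hypotheses about the arrest be tested from
one count matrix: a failed maternal-to-zygotic transition (MZT), chromosomal
aneuploidy, and a senescence-like shutdown of ribosomes, histones and the
cell cycle with disturbed glycolysis/oxidative-phosphorylation balance.

`embryoArrest` implements that analysis as a reusable pipeline. It starts
from a feature-by-sample matrix of raw counts in which features are genes
plus aggregated transposable-element (TE) types, together with a feature
annotation (gene/TE, chromosome, GC fraction) and a sample table
(developmental stage, normal/arrested/treated group). Every stage of the
pipeline is verifiable against a synthetic dataset with planted ground truth
(`simulate_dataset()`), which is also what the test suite and
`scripts/acceptance.R` use.

```{r, eval = FALSE}
library(embryoArrest)
p <- generator_params(seed = 1)
sim <- simulate_dataset(p)
res <- run_arrest_pipeline(sim$matrix, sim$annotation, sim$samples)
print(res)
```

## Normalization

Depth is removed with median-of-ratios size factors (the standard
reference-free estimator for count matrices), rescaled to geometric mean 1.

GC content biases library preparation smoothly and monotonically. The GC
correction here is within-sample full-quantile normalization across GC bins:
genes are split into `gc_bins` (default 10) equal-occupancy bins of GC
fraction and each bin's distribution is quantile-mapped, rank-preservingly,
onto the sample's pooled distribution; the sample is then rescaled so total
signal is unchanged. We chose full-quantile-in-bins over loess regression
because it is deterministic, has no smoothing hyperparameters, and is
idempotent up to order-statistic noise. That noise is the method's one
caveat: mapping a bin of ~600 genes onto pooled quantiles perturbs
individual values by a few percent even when no bias exists (the
perturbation scales with the expression spread divided by the square root of
the bin size), so the transform should be read as distribution-level, not
value-level, surgery. Aggregated TE types have no single GC fraction and
pass through with depth scaling only.

Downstream layers are `log2(NTC + 1)` ("normalized tag counts"; pseudocount
1 keeps zeros at zero) and per-feature Z-scores using the population
standard deviation (stable for small n, and what heatmap Z-scoring
conventionally does). Zero-variance features get all-zero Z-scores rather
than NaNs.

## Differential expression

`nb_wald_de()` is a deliberately simplified negative-binomial Wald test:
size-factor-normalized group means (floored at 0.5 so sparse features keep
finite fold changes), a pooled within-group method-of-moments dispersion
(variance = mu + dispersion x mu^2, floored at 1e-8), a delta-method
standard error for the log2 fold change, two-sided normal p-values and
Benjamini-Hochberg q-values. There is no dispersion shrinkage toward a
trend, no outlier replacement and no LFC shrinkage: the downstream logic
needs only the "at least 4-fold and q <= 0.01" flag, and the simplification
makes every number reproducible from this package alone. TE features run
through the same test as genes.

One definitional point: the power of the test "at 4-fold" is reported as the
probability of a q <= 0.01 call in the planted direction. A gene planted
exactly on the 4-fold line passes the fold filter itself only about half the
time, by symmetry of the estimator around the true value, so the filter is
not part of the power definition.

## MZT scoring

Major-ZGA genes are defined operationally as genes significantly
up-regulated more than 4-fold from the 2-cell to the 8-cell stage among
normal embryos, and maternal-clearance genes as those significantly
down-regulated; TEs are excluded (their dynamics are analysed separately).
The derivation uses only the 2-cell and 8-cell normal samples, so it cannot
be perturbed by which arrested embryos are present.

Each embryo then gets a ZGA score and a maternal score (mean Z over each
set) and a completion index (ZGA minus maternal). The flagging cutoff is the
midpoint between the median completion index of normal 4-cell and normal
8-cell embryos - the transition happens between those stages, and a midpoint
is symmetric and needs no tuning; it is exposed as an override.

Eligibility for flagging is chronological, which was a genuinely open design
point: arrested and treated embryos are by definition sampled on day 3-4,
past the time a normal embryo completes the MZT, so all of them are
eligible, and a pre-MZT expression placement in an arrested embryo is
exactly the failure signature being tested. Normal samples are eligible only
from the 8-cell stage on, so pre-MZT oocytes through 4-cell cells are never
called failures.

## Arrest typing

Arrested embryos are typed by co-correlation: Pearson correlation between
arrested samples over the most variable genes (default 2000, by log2-NTC
variance; the recovery properties hold for 1000-4000), then hierarchical
clustering of the correlation-matrix rows with Euclidean distance and
complete linkage, cut at k = 3. Distance on the correlation rows (rather
than 1 - r directly) treats each embryo's correlation profile as its
feature vector. Leaves are arranged by optimal leaf ordering (the standard
dynamic program over the dendrogram, minimizing the sum of adjacent-leaf
distances); this affects only display order and determinism of the reported
order, never memberships.

Each cluster is assigned its nearest developmental stage by running the DE
count against the normal samples of each candidate stage and taking the
argmin, with ties broken toward the earlier stage. The earliest cluster
becomes Type I, the remaining two become Types II and III in stage order
(size breaks stage ties). On the synthetic data this recovers Type I at the
4-cell stage, Type II at morula and Type III at E4.

## Expression karyotyping

Whole-chromosome gains and losses are inferred from dosage: each
chromosome's share of a sample's gene signal is compared against
stage-matched normal references (non-normal samples are referenced against
their nearest stage from typing), with a robust center (median) and scale
(1.4826 x MAD, falling back to the SD when the MAD is zero) because real
reference stages contain true aneuploids. |z| > 3 (default) calls a gain or
loss, and a sample is predicted aneuploid if any chromosome is called. Sex
chromosomes are included by default since the simulator does not model
embryo sex; on real data chrX/Y dosage confounds with sex and an
autosomes-only analysis is advisable.

A hard limitation worth stating precisely: with 24 chromosomes tested at
|z| > 3, even a perfectly calibrated Gaussian z-score leaves a per-sample
false-positive probability of 1 - (1 - 0.0027)^24 = 6.3%, and estimating
the center and scale from only 8 stage-matched references inflates the
per-chromosome tail far beyond its nominal level, so the sample-level
aneuploid fraction is substantially overestimated at this reference depth.
Event-level metrics (sensitivity for planted 1.5x/0.5x dosages,
per-chromosome false-call rate) are the reliable read-outs at desk scale;
trustworthy sample-level rates need tens of references per stage, as in the
published data sets this method is normally run on. Whole-chromosome events
only; segmental and mosaic (sub-embryo) events are out of scope.

## Signatures, metabolic coordinates and GSEA

Gene-set activity is the sum or mean of member Z-scores per sample
(`set_score()`), the reduction used for ranking embryos by
ribosome/nucleosome expression (arrested embryos sink to the bottom) or by
p53-target expression (arrested embryos rise to the top), and for the 2D
metabolic plane of glycolysis (x) versus oxidative phosphorylation (y). The
TE expression fraction is the percentage of normalized signal on TE
features, an indirect chromatin-state read-out that separates Type I
embryos from stage-matched normals.

`gsea_preranked()` is a classic weighted Kolmogorov-Smirnov enrichment
implementation: hit increments |metric|^p (p = 1 by default) normalized by
the set total, miss increments 1/(N - n), ES the maximal running-sum
deviation. Because only a ranking is available (not per-sample labels),
significance uses gene-label permutations - random same-size sets - with
NES = ES / mean(|ES| of same-sign permutations), a +1-corrected tail
p-value, and BH q-values over the tested sets. Ties in the metric are broken
lexicographically so results are bit-reproducible under a fixed seed. The
default ranking metric for contrast-driven GSEA is the signed Wald
statistic.

## What the simulator emulates, and what it does not

`generator_params()` defaults define the study conditions: 6000 genes spread
near-equally over 24 chromosomes plus 400 TE features; 11 stages (oocyte to
E7) with 8 embryos each; 23 arrested embryos planted as Types I/II/III =
10/7/6 and 4 treated embryos; negative-binomial counts (dispersion 0.1) with
log-normal depths (sigma 0.3) and a logistic GC bias (amplitude 0.3).

Parameter values the source data do not fix were chosen once, as realistic,
and not revisited:

* baseline expression log2-normal with mean 4.5 and spread 1.8 (a few
  hundred thousand counts per embryo at SMART-seq-like depth);
* maternal decay and ZGA steps uniform on 2.5-5 log2, so every planted gene
  clears the 4-fold rule by construction, with maternal clearance
  concentrated between the 2-cell and 8-cell stages;
* a smooth per-gene random walk with total drift 1.0 log2 across the axis;
* stage-marker programs (3% of genes each; a transient 4-cell program and
  persistent morula-E7 programs, effects 2.5-4 log2) - real adjacent stages
  differ by hundreds of strongly DE genes, and without them nearest-stage
  assignment would be degenerate;
* eight signature sets of 60 genes each. All three arrest types share the
  senescent core (ribosomes and nucleosomes down, p53 targets up, MYC
  targets down, CDKN1A up, CCNA2 down - CDKN1A and CCNA2 are named members
  of the p53/MYC sets so single-gene checks work); Type I adds 4-fold TE
  up-regulation and transcribes from the 4-cell profile with frozen MZT
  programs; Type II (morula profile) has glycolysis down and oxidative
  phosphorylation up; Type III (E4 profile) has both down and no nucleosome
  change; treated embryos (E5 profile) have glycolysis restored and
  fatty-acid genes up while ribosomes/nucleosomes and CDKN1A remain
  abnormal;
* 23 planted whole-chromosome events (gain 1.5x or loss 0.5x): one event in
  roughly 30% of normal embryos at the 8-cell stage and beyond and in 26% of
  arrested embryos, matching the rates the real data show.

The simulator does not model embryo sex, read-level artifacts, splicing,
allele-specific expression, mosaic (sub-embryo) aneuploidy, or cell-type
mixtures within an embryo, and its noise is a single global NB dispersion.
Passing recovery tests on it therefore demonstrates that the pipeline's
logic is correct and well-calibrated under its stated model - not that the
thresholds are optimal for any particular real data set.

## Problem sizes and reproducibility

The test suite runs the scaled-down fixture (600 genes, 4 embryos per
stage) for unit checks and the full-size fixture for recovery checks; the
recovery study (`evaluate_recovery()`) and `scripts/acceptance.R` use 20
independent seeds of the full-size fixture, 1000 gene-label permutations
for GSEA, and 50 replicates for the DE power study. All randomness flows
from the single seed argument; identical seeds give bit-identical matrices,
clusterings and GSEA results.
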