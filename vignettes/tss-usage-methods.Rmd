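---
title: "Methods: TSS cluster prediction, adjustment, and differential usage testing"
author: "tssUsage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS cluster prediction, adjustment, and differential usage testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`tssUsage`, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data tests do and do
not establish about real data.

## Data model and coordinate conventions

All coordinates are 1-based and fully closed internally (the GTF
convention); BED input and output convert to and from 0-based half-open at
the file boundary. A *mapped-TSS table* is the compact exchange format
between alignment and clustering: a tab-separated file of
chromosome / position / count / strand, optionally followed by a cell
barcode column. Working from tables rather than whole BAM files keeps
memory flat during clustering of large single-cell samples; the BAM step
(`extractMappedTss()`) only extracts 5' ends — the leftmost aligned base
on `+`, the rightmost on `-` — deduplicating to one count per UMI per
position per cell when UB tags are present.

Two data layouts are supported. In *on-site* (paired-end) data the 5' end
of Read 1 marks the genuine TSS and is used directly. In *near-site*
(single-end) data only Read 2 carries cDNA; its 5' end sits a fragment-
length-dependent distance 3' of the genuine TSS, and clusters of such ends
must be shifted before they can be interpreted as TSS clusters (below).

## Cluster prediction and merging

Per sample, `clusterTss()` performs simple distance-based clustering:
positions with at least `minPosCount` reads (default 3) on one
chromosome/strand are chained while consecutive kept positions are at
most `maxGap` bp apart (default 20), and chains with at least
`minClusterCount` total reads (default 5) become clusters. The defaults
are modeled on common distance-clustering settings for 5'-end data (count
threshold 3, chaining distances of a few tens of bp) and are all exposed
as arguments. The *dominant TSS* of a cluster is its highest-count
position; ties break toward the 5' end in transcript orientation (the
most upstream position), a convention this package fixes because the
underlying definition is silent on ties.

Clusters predicted in different samples overlap imperfectly even when
they represent the same promoter. `mergeClustersDisjoin()` pools all
per-sample clusters and partitions them with `GenomicRanges::disjoin`
into the minimal set of non-overlapping intervals that respects every
input breakpoint; `+` and `-` clusters never merge. A unified
(post-disjoin) cluster no longer has a unique parent, so its gene
assignment is recomputed from the unified interval's midpoint — the
least-committal reference point for an interval without per-position
counts. Gene assignment (`assignGene()`) matches the cluster's reference
point (dominant TSS for on-site data, read-weighted center for near-site
data, midpoint for unified clusters) to the same-strand gene whose span,
extended upstream by a promoter window `W` (default 1,000 bp, matching
the adjustment horizon below), contains it; among several candidates the
gene with the nearest annotated transcript start wins. Opposite-strand
genes are never considered.

## Near-site adjustment

Near-site clusters centered in introns indicate transcripts missing from
the annotation; since their genuine TSS cannot be located they are
excluded (`filterIntronicNearsite()`). Intergenic centers are *not*
intronic and pass through.

The shift applied to the remaining clusters is learned from genes with a
single annotated TSS: for each such gene the smallest distance between
any near-site cluster center and the annotated TSS is computed, distances
above 1,000 bp are discarded as likely unannotated TSSs, and the
read-count-weighted mean of the rest is the *adjustment distance*
(`learnAdjustmentDistance()`). Three conventions had to be fixed here:

* a cluster *center* is its read-count-weighted mean position, rounded to
  the nearest integer (the notion is otherwise undefined for multi-
  position clusters);
* distances are measured in transcript coordinates, consistent with the
  intron-aware shift they calibrate (genomic distance is the fallback
  when either endpoint is not exonic in the chosen transcript);
* when several transcripts of the gene contain the center, the one whose
  annotated start is most 5' is used — it maximizes the room available
  for upstream shifting.

`adjustClusters()` projects each center into transcript coordinates,
shifts it 5' by the adjustment distance (clamped at transcript position
1), and projects back through the exon chain, so introns between source
and target are skipped. Clusters whose center is in no exon of their
gene's transcripts fall back to a genomic-coordinate shift with a
warning. Adjusted clusters keep their original width, centered on the
new position: nothing in the calibration constrains how widths
transform, so the least-surprising choice is to preserve them. The
original intervals are retained (`origStart`/`origEnd`) because
quantification of near-site data counts Read-2 ends in the *original*
near-site intervals while reporting the adjusted rows, in 1:1
correspondence.

## Quantification and usage

`quantifyClusters()` counts, per cell, UMIs whose 5' end falls inside
each unified cluster — intervals closed on both ends, strands matched —
into a sparse cluster × cell matrix (`TssCountMatrix`, a
`RangedSummarizedExperiment`). Counting refuses overlapping intervals,
which would double-count; unified clusters from `mergeClustersDisjoin()`
are disjoint by construction. Usage of cluster *t* on a gene is
θ~t~ = x~t~ / Σ~t'~ x~t'~; a zero denominator leaves the usage undefined
(`NA`), never zero. Cell quality control is deliberately out of scope:
the package consumes whatever barcodes upstream filtering produced.

## The binomial GLMM

For one cluster, with x the cluster count, y the gene total, and
condition coded by dummies z:

$$x_{ij} \sim \mathrm{Binomial}(y_{ij}, \theta_j), \qquad
  \mathrm{logit}(\theta_j) = \beta_0 + z_j^\top\beta + \phi_j, \qquad
  \phi_j \sim N(0, \sigma^2).$$

Modelling the *proportion* x/y rather than the count x makes the test
robust to differential gene expression between the conditions, which
changes y but not θ. The per-sample random intercept φ absorbs donor-
level heterogeneity, which is exactly what the simulation's outlier
mixture stresses.

Estimation (`fitBinomGlmm()`) integrates φ out by a Laplace
approximation — the integral factorizes over samples, each factor's mode
is found by a safeguarded Newton iteration on a strictly concave
1-D problem — and maximizes the resulting profile over (β, log σ) with
`nlminb` (relative tolerance 1e-12, 500 iterations). Convergence is
confirmed by a restart from the solution: `nlminb` sometimes reports
"false convergence" in the flat log-σ direction at a perfectly good
optimum, and a restart that cannot improve the objective settles the
question. Starting values come from an ordinary binomial GLM. The
σ → 0 limit is smooth (the Laplace correction vanishes), and a
`sigma2Fixed = 0` mode drops the random effect entirely, reproducing a
plain GLM — the cross-check used in the tests. Non-convergent fits are
reported as such with a missing p-value, never silently coerced to 1.

The DU test is a likelihood-ratio χ² test with K − 1 degrees of freedom:
the null model omits the condition dummies but keeps covariates and the
random intercept. σ² is a nuisance present under both hypotheses, so the
boundary problem that afflicts tests *of* σ² does not arise for the test
of β and no boundary correction is applied. Cells with y = 0 contribute
no likelihood and are dropped. The cell-level likelihood is the literal
product of per-cell binomials — cells are weighted by their gene counts,
as the binomial dictates.

Because all cells of a sample share θ~j~, their binomial likelihoods
aggregate: the cell-level and pseudo-bulk fits maximize the same function
up to a data constant and return identical estimates and p-values to
numerical precision. The package's tests verify agreement below 1e-4
across a full simulated study; pseudo-bulk is the default because it is
two orders of magnitude faster.

Comparators: `wilcoxonDu()` applies the two-sided rank-sum test directly
to usage values (per cell, or per sample on aggregated-count ratios);
`ideasModifiedDu()` computes per-sample empirical usage distributions and
tests the mean between-group minus within-group pairwise Wasserstein-1
distance by permuting sample labels (default 2,000 permutations, p =
(1 + #{perm ≥ obs}) / (1 + n~perm~)). Note the granularity of a label
permutation test: with 3 + 3 samples only 20 label assignments exist and
p below ~0.1 is unattainable; sample sizes of 4 + 4 or more are needed
for rejection at 0.05. Multiple testing uses Benjamini-Hochberg
(`stats::p.adjust`) across all tested clusters.

Before testing, genes are filtered (`filterGenes()`): detection (gene
total > 0, pooling the compared cell groups) of at least 10% of cells in
*every* sample — boundary inclusive — and at least two clusters, since a
single-cluster gene has constant usage 1. Both knobs are arguments.

## Simulation design

The benchmark generator (`simulateDuDataset()`) assumes two biological
conditions with J samples each, I cells per sample, and two TSS clusters
per gene. Gene-level counts are independent negative binomials per gene
and cell; means and sizes are drawn from log-normal hyperpriors
(meanlog log 2 / sdlog 0.8, and meanlog log 2 / sdlog 0.5) chosen to
resemble the moderately-to-well-detected genes that survive
detection-rate filtering of 5' single-cell data, and a configurable
fraction of genes (default 20%) receives a condition-specific log-normal
fold change to emulate confounding differential expression. Correlation
between genes is deliberately omitted: every DU test operates marginally
per gene, so gene-gene dependence does not enter any likelihood being
evaluated.

Expected usage per sample: null genes share a baseline
a ~ U(0.1, 0.9) across conditions; alternative genes have baselines
a₁ ~ U(0.1, 0.4) and a₂ = a₁ + d with d ~ U(0.1, 0.5). Sample offsets τ
follow outlier mixtures: under the null
(1 − π) U(−0.1, 0.1) + (π/2) U(c₁, c₂) + (π/2) U(−c₂, −c₁); under the
alternative the outlier component is one-sided positive,
(1 − π) U(−0.1, 0.1) + π U(c₁, c₂), *in both conditions*. The one-sided
form shifts E[τ] slightly, and a `symmetricOutliers` switch provides the
symmetric variant, but the one-sided mixture is the default by fidelity
to the design being reproduced. Expected usages μ = a + τ are clipped to
[0, 1] exactly. Cell-level usage is γ ~ Beta(α, 5) with
α = 5μ/(1 − μ), so E[γ] = μ; a clipped μ of 0 or 1 makes the Beta
undefined and degenerates to a point mass. Cluster-1 counts are
Binomial(gene count, γ) and cluster 2 receives the complement.
Benchmarks (`evaluateDuMethods()`) report type I error and power as
rejection fractions of null and alternative genes at BH-adjusted
p < 0.05, with failed fits counted as non-rejections.

The grid actually exercised by the package's tests is a reduced version
of the full design — J = 10, I = 100, 500 + 500 genes for type I error
across π ∈ {0.1, 0.3} and both deviation settings, and J = 5, I = 100,
200 + 200 genes for the cell/bulk agreement check — sizes chosen so the
whole suite runs in minutes on one CPU while keeping the Monte-Carlo
standard error of a 5% rejection rate below one percentage point.

## Synthetic fixtures: what they show and what they do not

`makeAnnotation()` lays out non-overlapping 1-3-exon genes on a toy
chromosome; a configurable fraction get a second transcript starting
150-400 bp (transcript space) into the first exon, giving two true TSSs.
`makeOnsiteReads()` places read 5' ends at true TSSs with Gaussian jitter;
`makeNearsiteReads()` displaces them 3' by |N(mean, sd)| in transcript
coordinates and projects through the exon chain, so displaced positions
are always exonic. Barcodes mimic 10x style. Jitter and displacement are
Gaussian for simplicity; empirical 5'-end displacement distributions in
real libraries are heavier-tailed and asymmetric, and none of the
library-specific artifacts (strand invasion, the extra templated G at the
5' end, ambient RNA, doublets) are modeled. Passing the fixture tests
therefore establishes the *correctness of the computations* — recovery of
known TSSs, usage shares, and displacement distances under the stated
noise — not the field performance of the clustering heuristics on real
libraries, which depends on artifact structure the fixtures do not
emulate.

## Known limitations

* No removal of strand-invasion artifacts or the reverse-transcription
  G at the 5' end; upstream tools must handle these, and positions one
  base off may slightly blur clusters otherwise.
* The near-site adjustment depends entirely on the exonic annotation:
  intron-centered clusters are dropped rather than interpreted, and a
  single global adjustment distance is used rather than a per-fragment
  probabilistic model.
* DU testing after data-driven cell clustering is exploratory: no
  post-selection correction is applied.
* Gene-level precision for a gene with no predicted clusters is
  undefined and excluded from the precision mean (its recall still
  counts); sample-level precision/recall are unweighted means over
  genes, and distance summaries use the sample (n − 1) standard
  deviation.
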