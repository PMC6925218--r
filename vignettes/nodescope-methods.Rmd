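---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind each stage of the
pipeline, the tunable parameters and why their defaults are what they are,
what the synthetic cohort generator does and does not emulate, and the
numerical decisions taken where the design was genuinely open.

## The data model

The unit of input is a digital gene expression (DGE) matrix: genes ×
barcodes, nonnegative integer UMI counts, carried as a
`SingleCellExperiment` whose `rowData` flags each gene's species,
mitochondrial status and transgene status, and whose `colData` records the
animal (replicate) and treatment arm of each barcode. The animal is the
statistical unit of every cohort-level claim: population fractions are
normalized to the total number of cells per animal before any ANOVA or
t-test, so cells never masquerade as replicates. The one deliberate
exception is the ANCOVA treatment-interaction test on imputed expression,
which treats cells as observations; its result object carries an explicit
pseudo-replication caveat.

## Quality control

Barcodes pass four families of criteria, applied species → cell → gene:

* **Species purity** (barnyard design): the target-species count fraction
  must *strictly* exceed `speciesPurity` (default 0.90). A barcode at
  exactly the threshold is removed. Foreign-species gene rows are dropped
  afterwards.
* **Content floors**: more than 500 UMIs *and* more than 500 detected
  genes (both strict: a 500-count barcode is removed). The floors are
  full-transcriptome conventions; on the reduced synthetic gene panel
  (~1,150 genes) the test suite scales the gene floor to 150 and says so
  wherever it does.
* **Upper outliers**: total counts, detected genes and the mitochondrial
  count *fraction* must not exceed center + multiplier × SD, computed per
  batch (one animal's sample). The center is the median and the spread the
  classical SD about the mean — the conventional description mixes the
  two, so both are configurable (`center = "median"|"mean"`). The
  multiplier conventionally lies between 4 and 5; the default is 4.5, and
  the configuration validator warns (but does not refuse) outside that
  range. The criterion targets the mitochondrial *fraction*, not raw
  mitochondrial counts, because dying cells are characterized by a
  disproportionate share of mitochondrial transcripts.
* **Gene floor**: a gene must be detected (count > 0) in at least 30
  barcodes; transgene-flagged genes are exempt because lineage calls need
  them even when rare. The gene floor and the per-barcode gene floor are
  computed independently on the raw matrix.

Two small-sample facts are worth knowing. With SD taken about the mean on
a batch of n barcodes, a single outlier's deviation is algebraically
bounded near `sqrt(n)·(1 - 1/n)` SD — about 4.47 at n = 20 — so a 4.5
multiplier can never flag one outlier in a 20-barcode batch; the QC fixture
in the test suite therefore uses multiplier 4 (inside the 4–5 convention).
And when a batch is perfectly homogeneous (SD = 0) the strict `>`
comparison removes nobody, which is the intended degenerate behavior.

Normalization is per-cell scaling to `scaleTotal` (default 10,000) followed
by log1p. The upstream convention leaves normalization unstated;
this is the field-standard choice and is recorded in the object's
metadata. Zero counts map to zero and the transform is invariant to
scaling all counts of a barcode.

## Dimensionality reduction and component selection

Variable genes: per-gene mean and dispersion (variance/mean) of the
normalized values; genes sorted into `nBins = 20` equal-width mean bins
(unstated upstream; 20 is the common default) and dispersion z-scored
within bins; selection requires mean in (0.125, 3) and z ≥ 0.5. The
binned z-score is *relative*: it assumes bins are populated mostly by
uninformative genes against which markers stand out, which holds for real
transcriptomes and is reproduced in the generator by a dedicated
background block.

PCA: genes centered and unit-scaled across cells, then a *complete* SVD —
the component-selection rule z-scores each component's share of variance
over the full spectrum, and truncating the spectrum inflates the
denominator enough to swallow real components. Embeddings are the SVD
scores UD (equivalently scaled expression × loadings), so each column
already carries its component's singular-value weighting; distances in
"PC space" therefore weight components by their standard deviation.
Component signs are fixed by making the largest-magnitude loading
positive. Significant components are those with variance z-score > 2;
batch-tracking components are excluded by an explicit user-supplied list
(mirroring manual batch rejection; no automatic batch detection is
attempted).

## Clustering, t-SNE, nodes

The SNN graph uses k = 30 neighbors (including the cell itself),
Euclidean distance in significant-PC space, edge weight = Jaccard index
of the two neighbor lists, and pruning below 1/15. Louvain modularity
maximization runs at resolution 0.8. Neighbor search is exact (chunked
full distance computation) with ties broken by cell index, which makes
clustering reproducible to the byte under a fixed seed. One structural
caveat: modularity can never merge *disconnected* graph components, so
the resolution → 0 limit reaches a single cluster only on SNN-connected
data; the test suite checks the limit on adjacent blobs for that reason.

t-SNE is a visualization device only (perplexity must be below
n/3; all statistics run in PC or IC space). Node merging applies average
linkage (recorded in the result; the upstream tool default is
unspecified) to cluster centroids in significant-PC space and cuts the
dendrogram into the requested number of groups, optionally restricted to
a designated subtree — the multi-cluster tumor complex — leaving outside
clusters as singleton nodes. Nodes are named A, B, C… in dendrogram leaf
order.

## Differential expression and doublet clusters

The per-gene model is a mixture of a point mass at zero and a log-scale
normal for positive values; the LRT compares a pooled fit against
separate per-group fits (3 parameters per group) on a chi-squared with
3 df. Plug-in variance estimates inflate the statistic at small expressed
counts, so the statistic is deflated by a Bartlett-type factor
`1 + 0.6·(1/n1A + 1/n1B)` where `n1` are per-group expressed-cell counts;
the correction was calibrated on null simulations across group sizes
30–200 and holds the empirical type-I error at nominal 5 % with uniform
p-values. The log fold-change is the difference of group mean normalized
expression with zeros included. All p-values are Benjamini–Hochberg
adjusted (the upstream correction is unstated; BH is the field default).

Doublet clusters are flagged by the classic co-capture signature: against
*both* members of a candidate parent pair, at least `nMin = 50` genes
significant at adjusted p < 0.05 with |logFC| < 0.5 and detection
fraction > 0.25 in both groups. Those thresholds are made explicit here
because the upstream description ("many genes… low fold-change… high
percent") quantifies none of them. Two containment checks then arbitrate
between candidate pairs, exploiting the fact that a doublet's counts are
the sum of its parents': each parent may broadly express (pct > 0.6) at
most `missMax = 5` genes the candidate lacks (pct < 0.4), and the pair
jointly must account for the candidate's transcriptome (at most
`orphanMax = 5` genes with pct > 0.6 in the candidate but < 0.3 in both
parents). The asymmetric pct cutoffs leave headroom for ambient-RNA
background detection, which doubles in doublets along with everything
else. On continua the low-fold-change signature is intrinsically
ambiguous — an intermediate differentiation state *is* approximately the
average of its neighbors — so flags on trajectory clusters warrant manual
review, exactly as in the original workflow.

## Reference projection

A fitted reference carries its variable genes with centering/scaling
constants, gene loadings, significant components, 2-D layout and labels.
Query cells are embedded by restricting their normalized expression to the
reference's variable genes (a missing gene contributes the centered value
of a zero count, keeping embeddings comparable across queries with
different coverage), applying the reference's constants, and multiplying
by the loadings — directly comparable to the reference's UD scores.
Placement averages the layout coordinates of the K = 5 nearest reference
cells in significant-PC space (exhaustive search, ties broken by
reference index); labels transfer by majority vote with the vote fraction
as confidence, ties resolved in favor of the nearest neighbor's label.
The source method is described with both K = 5 and K = 3 in different
places; K is configurable, defaults to 5, and the result object's notes
record the convention.

## ICA trajectory and cell-cycle scoring

ICA runs on variable genes × cells, z-scaled per gene (the upstream input
scaling is unstated; z-scaling makes the contrast scale-free), using
fixed-point negentropy maximization with logcosh contrast in deflation
mode under a fixed seed. With `nComponents = "auto"` the component count
equals the number of significant PCs (z > 2) of the same input. Components
are sign-oriented so the heavier (skewed) weight tail is positive, and
scores are rescaled to unit sample variance. The differentiation
component is the one whose top-50 positive tail is most enriched for
differentiation markers (minus enrichment in the negative tail, and
penalized by proliferation markers when supplied), evaluated in both
orientations; ties go to the lower index.

Cell-cycle phase scores are means of across-cell z-scored expression over
phase gene lists; the assigned phase is the argmax, and a cell with no
positive score is "low-cycling" (this covers the all-identical degenerate
input, where every z-score collapses to 0). A small editable YAML of
canonical murine cycle genes ships as the default resource; the original
study's lists derive from prior published work and are not reproduced.

## Imputation and treatment interaction

The diffusion operator is built from the k = 12 nearest neighbors (the
count the upstream analysis found appropriate), an adaptive Gaussian
kernel with per-cell bandwidth equal to the distance to the ⌈k/3⌉-th
neighbor, symmetrization, and row normalization; duplicated points
(bandwidth 0) receive uniform affinity over their neighborhood. Imputed
expression is operator^t × values; t defaults to 3 and is reported in all
output metadata. Diffusion is a contraction — per-gene variance is
non-increasing in t — and fixes constants exactly. The appropriate t
grows with dropout severity: the dropout-recovery demonstration in the
test suite (60 % dropout) uses t = 9, because at that dropout level the
narrow adaptive kernel needs more steps to pool enough neighbors for the
Bernoulli sampling noise to average out.

Correlation uses Pearson r with the t-distribution test
(t = r·sqrt((n−2)/(1−r²)), two-sided); zero-variance input yields a
flagged NA rather than a number. The treatment interaction is
`target ~ regulator × arm` by OLS with the interaction F-test, reported
with per-arm slopes and the pseudo-replication caveat noted above.

## Cohort statistics

Fisher's exact test uses the standard two-sided convention — the sum of
probabilities of all tables with the observed margins no more probable
than the observed table — with the conditional maximum-likelihood odds
ratio; conventions differ between implementations, so this one is stated.
The hypergeometric overlap test is upper-tailed: P(X ≥ observed). Fold
changes are reported both as the ratio of arm means and as the mean of
per-animal ratios with its SEM, because the two differ and published
fold-change figures do not always say which was used. The two-way ANOVA
on marker-positive rates uses cluster-group and animal as fixed factors
(the second factor is an interpretation: replicate identity is the only
other design variable available), with Bonferroni-adjusted pairwise group
contrasts.

## What the synthetic generator emulates — and what it does not

The generator draws each cell's library size from a negative binomial
(mean 2,000, size 8; a per-animal log-normal scalar of SD 0.1 is the only
batch effect) and allocates it multinomially over a composed gene
probability vector. The panel (~1,150 genes) contains housekeeping and
low-expression background blocks shared identically by all populations;
"graded" genes whose per-population weight is 1× or 2.1× a common base
(these create realistic correlated between-population shifts and the
intermediate-dosage genes that make doublets detectable); exclusive
marker blocks (30 genes per stromal population); three 60-gene
stage-specific trajectory waves whose piecewise-linear profiles
(early max(0, 1−2t), mid 1−|2t−1|, late max(0, 2t−1)) sum to constant
mass, switching on and off between adjacent differentiation stages; four
8-gene cell-cycle phase sets expressed on a cyclic latent angle by 60 %
of early-pseudotime cells; 10 mitochondrial genes; a *Yfp* transgene; 100
human genes for the spike-in; and a regulator/target pair whose weights
are modulated by a per-cell latent factor with an arm-dependent sign.

Pseudotime is a three-bump Beta mixture (centers 0.12/0.50/0.88,
concentration 100) — metastable states along a continuum — with
arm-specific tier weights (vehicle 0.45/0.35/0.20, treated
0.15/0.30/0.55) and a treated-arm multiplier of 0.6 on the tumor
population, emulating depletion of proliferative tumor cells and a shift
toward differentiation under treatment. Mitochondrial fractions follow
Beta(2.5, 60) with a 2 % Beta(18, 12) stressed tail ("predominantly
mitochondrial" dying cells). Doublets are same-animal column sums at rate
0.05; ambient admixture is 2 % of each cell's probability mass from the
pooled profile; 5 % of barcodes are pure-human spike-ins. Lineage
reporter probabilities are 0.8 for the tumor continuum, 0.15 for
astrocytes and oligodendrocytes, 0 elsewhere — the pattern that makes
glial lineage expansion detectable.

Relative signal amplitudes were set so that, as in real tumor data, the
differentiation program dominates the cell-cycle program in PCA space
(log-normalization caps every on/off gene near the same amplitude, so
what matters is how many genes move along each axis and how strongly they
are expressed); with the defaults above, the significant-PC rule finds
7–10 components, Louvain at 0.8 yields ~10–14 clusters, and centroid HCA
recovers the three tiers as nodes.

Not emulated: read- and UMI-level artifacts (barcode errors, UMI
collision), chemistry batch effects beyond the per-animal scalar,
cross-species chimeric doublets, ambient profiles that differ between
animals, and any transcriptome-wide gene count. Passing recovery tests
on this generator therefore demonstrates the pipeline's correctness on
data with the assumed structure, not robustness to artifacts outside it.

## Problem sizes and determinism

The test suite validates cluster/node/IC recovery on five independent
two-arm cohorts of ~3,000 cells, doublet-cluster recall on twenty
3-population cohorts (~400 cells) with 10 % targeted hybrids plus five
hybrid-free cohorts, DE calibration on 100 null replicates of 200 genes
at 100 cells per group, correlation calibration on 1,000 null replicates
at n = 1,000, and the treatment sign-flip on ten reduced cohorts
(~650 cells). These sizes were chosen as the smallest at which the
cohort-level effects are comfortably identified. Every stochastic
stage takes an explicit seed; the pipeline driver derives per-stage seeds
from one global seed and reproduces analysis outputs byte-for-byte (the
run log contains wall-clock timings and is the one file excluded from
that guarantee).

## Known limitations

* The bimodal LRT's chi-squared reference is approximate for genes
  expressed in very few cells even after the finite-sample correction;
  with fewer than ~20 expressed cells per group its p-values should be
  treated as heuristic ranks.
* The doublet heuristic cannot distinguish a genuine intermediate state
  from a doublet of its neighbors on a continuum; it is a screen, not a
  verdict.
* Reference projection assumes the query's expression scale matches the
  reference's normalization; it does not correct batch effects (anchor- or
  CCA-style integration is deliberately out of scope).
* The ANCOVA treats cells as independent; with few animals per arm a
  mixed model would be more conservative, but is not what the original
  analysis used.
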