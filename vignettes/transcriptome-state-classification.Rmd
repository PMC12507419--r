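---
title: "Classifying transcriptomes into physiological states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptomes into physiological states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txclass)
```

## The problem

Bulk RNA-seq collections assembled from many studies — say, long-lived
*C. elegans* mutants spanning reduced insulin/IGF-1 signaling (rIIS),
dietary restriction (DR), and reduced mitochondrial function (rMF), or
senescent cell lines induced by different stressors — carry a labeled
*physiological state* per sample. Two questions recur: which minimal set of
genes separates those states, and to which state does a new (query)
transcriptome belong? `txclass` answers both with deliberately simple,
deterministic statistics: ANOVA F-ranking with an elbow cutoff for gene
selection, classical MDS for visualization, the mean silhouette width for
grading separation, and Spearman correlation for query assignment.

## The selection model

For each gene the one-way ANOVA F-value is computed across the $K$ state
categories,

$$F = \frac{\mathrm{SS}_{\text{between}}/(K-1)}
           {\mathrm{SS}_{\text{within}}/(N-K)},$$

on variance-stabilized expression. $F$ measures how far the category means
sit apart relative to replicate noise, so genes with large $F$ discriminate
the states. Genes are ranked by descending $F$; a gene with zero
within-category variance but distinct means is a perfect separator and gets
$+\infty$ (sorting first), a gene constant everywhere gets $0$. Ties break
by gene id so the ranking is reproducible.

The *optimal gene set* is cut at the elbow of the ranked-F curve: the chord
is drawn from the first to the last point, the rank at maximum
perpendicular distance from that chord is the elbow, and all genes with F
strictly above the elbow gene's F are selected. Three numerical choices
make this well defined:

* **Axis scaling.** A perpendicular distance mixes the rank axis with the F
  axis, so it depends on their units. Both axes are min-max scaled to
  $[0,1]$ before the geometry, which makes the elbow invariant to the
  absolute F scale. (Whether to scale at all is a genuine free choice; the
  unscaled version makes the elbow drift with the largest F, which is
  undesirable for a cutoff rule.)
* **Infinite sentinels.** $+\infty$ F-values are clamped just above the
  largest finite F so the chord construction stays finite while rank order
  is untouched.
* **Ties and degeneracy.** Distances within $10^{-12}$ of the maximum are
  tied and the smallest rank wins; an exactly linear curve (all distances
  zero up to float noise) therefore yields rank 1 with a warning, and the
  elbow gene itself is selected when the strictly-greater set is empty.

Two baselines ship alongside: `variance_topk_select` (the unsupervised
top-$k$-variance default of MDS front-ends, $k = 500$) and
`shadow_feature_select`, a Boruta-style procedure that, per iteration,
appends a permuted "shadow" copy of every gene, fits a randomized-tree
ensemble on real + shadow features, and scores a hit when a real gene's
impurity importance beats the best shadow; genes whose hit counts beat a
$\mathrm{Binomial}(n_{\text{iter}}, 1/2)$ upper tail at level $\alpha$
(default 0.05) are Confirmed. All of its randomness flows from one seed.

## Preprocessing

The transform chain feeding those statistics is conventional:

1. **Prefilter** — keep genes with $\ge$ 1 read in $\ge$ 80% of samples
   (boundary inclusive). Both thresholds are arguments.
2. **Size factors** — median-of-ratios against per-gene geometric means;
   an upper-quartile rescaling is available for datasets whose count
   distributions are too skewed for it (caller names those datasets).
3. **Variance stabilization** — the shifted log
   $\log_2(\text{count}/s_j + 1)$. A dispersion-trend VST would differ in
   the low-count regime, but every downstream statistic here is either
   rank-based (Spearman) or location/scale-free per gene (F), so the
   stand-in changes little; it is exactly monotone per sample, which the
   rank statistics require and which makes its choice largely immaterial to
   classification.
4. **Batch correction** — per-gene least squares on batch indicators plus
   category indicators (category retained so biology is not absorbed;
   `retain_category = FALSE` drops it). Batches are treatment-coded against
   the first batch, so samples are corrected *toward the reference batch*
   and an injected additive offset is removed exactly; sum-to-zero codings
   differ only by a per-gene constant. A perfectly confounded batch/category
   design is refused with an error.
5. **Replicate collapse** — dataset-level analysis (the default) averages
   replicate columns per dataset after normalization and batch correction,
   so each study counts once in the ANOVA and in cross-validation;
   `level = "sample"` switches to per-sample analysis.

## Projection, scoring, classification

Classical (Torgerson) MDS embeds the Euclidean distance matrix over the
selected genes: $B = -\tfrac12 J D^{(2)} J$, eigendecomposition, top-2
eigenvectors scaled by $\sqrt{\lambda}$. Negative retained eigenvalues are
truncated to zero with a warning (the full spectrum is kept as a
diagnostic), each axis is signed so its largest-magnitude coordinate is
positive (determinism), and the relative residual between input and
embedding distances is reported as `stress`.

The **clustering score** is the mean silhouette width of samples under
their category labels, computed on the 2D coordinates — it grades the plot
a user actually looks at; pass a full distance matrix to score the
unreduced space instead. Singleton categories contribute 0.

A **query** is assigned by Spearman correlation (mid-ranks, pairwise-complete
over positions missing in either vector, $\ge 3$ complete pairs required)
against every reference column over the selected genes; each category is
summarized by its mean rho ± SEM and the argmax wins. When the top two
category means sit within 0.01 of each other the call is flagged ambiguous
and all tied categories are reported — differences at SEM scale should not
look like decisions. The query is placed on the map by *joint* re-embedding
(reference + query), which can shift the reference geometry slightly; the
run manifest records that placement is joint, not out-of-sample.

## Evaluation protocol

`loocv` holds out one unit (dataset by default) at a time, **reruns gene
selection on the remaining reference only** — the held-out unit can never
leak into the gene set — and classifies it. Folds whose removal would empty
a category are skipped and excluded from the denominator; folds whose
selected set is too small to correlate over count as incorrect
(abstentions). `subsample_robustness` repeats LOOCV on stratified random
subsamples at 100/80/60/40/20% of the reference (10 repeats per
proportion; per category, round-half-up with a 1-unit floor so no category
vanishes — a reference without a category cannot classify into it).
Proportion 1.0 reproduces plain LOOCV exactly. The "repeated random
subsample" reading of the protocol, rather than a 10-part partition, is
deliberate: it is the only reading under which 100% subsampling is well
defined, and the repeat count is an argument.

## What the simulator emulates — and what it does not

`simulate_counts` draws negative-binomial counts with mean
$\exp(\text{base}_g + \text{effect}_{g,c} + \text{batch}_b +
\text{lib}_s)$ and a gene-shared dispersion. The default scenario mirrors a
multi-study reference: 3 categories × 9 datasets × 3 replicates (81
samples), 5000 genes, 100 informative genes per category (disjoint,
up/down at random) shifted by 2 within-group SDs on the log scale, 3
batches assigned round-robin over datasets so batch stays balanced across
categories.

Free parameters were fixed once at values typical of bulk RNA-seq and are
not tuned per analysis: dispersion 0.1 (mid-range for heterogeneous bulk
collections), baseline log-means uniform on $\log 5 \ldots \log 500$
(most genes comfortably above the prefilter), batch offsets
$\mathcal{N}(0, 0.1)$ on the log scale, library factors log-uniform within
$\pm 0.3$ (≈ 0.74–1.35×). Effect sizes are expressed in units of the
gene's own within-group log SD ($\sqrt{1/\mu + \phi}$ by the delta
method), so "effect 2" means a shift of twice the replicate noise
regardless of expression level.

The generator deliberately omits: per-gene dispersions, correlated gene
modules, partially overlapping informative sets, gene-length effects,
batch-by-category interactions, and single-cell dropout. Consequently a
passing recovery suite demonstrates that the algorithms are implemented
correctly and behave as designed under their own model assumptions — not
that real multi-study collections, whose unwanted variation is richer than
an additive batch offset, will classify at the same accuracy.

## Validation problem sizes

The test suite validates against brute-force oracles (textbook ANOVA sums
of squares, exhaustive chord-distance search, the silhouette formula,
rank-then-Pearson on complete pairs, Procrustes alignment of planted 2D
configurations) and against planted truth: on the default scenario the
elbow selection is required to reach precision ≥ 0.8 and recall ≥ 0.9 and
LOOCV accuracy 1.0, with label-shuffled LOOCV at chance. Stochastic
properties use fixed seed grids — 10 seeds for the optimal-versus-top-500
comparison and the subsampling degradation trend (the latter on a
lower-powered scenario: effect 1 SD, 2000 genes, 8 datasets × 2 replicates
per category), 5 seeds for the zero-effect F-calibration, 10 seeds for the
shadow-selection null. These sizes were chosen so the whole suite exercises
every claim at meaningful power while remaining a desk-scale run.

## Known limitations

* The elbow is a geometric heuristic: on curves without a clear knee it
  selects very few genes, and downstream Spearman classification needs at
  least 3 shared genes (see the abstention policy above).
* Query placement is joint re-embedding, not out-of-sample projection; with
  a query far from the reference cloud, reference coordinates shift.
* The shifted-log stand-in for a dispersion-trend VST slightly inflates the
  variance of very low-count genes; with the default prefilter this is
  visible only as a mildly heavy upper tail in the null F distribution
  (measured ≈ 6% beyond the theoretical 95th percentile).
* Dataset-level analysis treats each dataset's mean as one exchangeable
  unit; datasets with very different replicate numbers are not reweighted.
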