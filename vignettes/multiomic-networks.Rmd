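---
title: "From multi-omic blocks to functional regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-omic blocks to functional regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicnets)
```

## The problem

Tumour cohorts profiled on several molecular layers at once — CpG
methylation arrays, RNA-seq, miRNA-seq — carry regulatory signal that no
single layer shows: a methylated promoter that silences a transcript, a
miRNA that degrades its targets, a transcription factor that drives a
module. `omicnets` turns three sample-aligned feature matrices into
function-level regulatory network models in a semi-automated chain:
preprocessing, sparse multi-block factor extraction, stability selection,
enrichment, mutual-information network inference with prior-calibrated
thresholds, topology summaries, CpG regulatory-element classification, and
Cox screening of the recovered interactions.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Preprocessing

Count blocks lose features that are zero in every sample (the weakest
defensible reading of a "zero-count filter"; a CPM-style option would be a
one-line extension, but the default deliberately removes only
uninformative rows). Transcripts are TMM-normalized (edgeR's doubly
trimmed, precision-weighted mean of log-ratios: 30% trim on M, 5% on A,
reference sample with upper quartile closest to the mean upper quartile);
miRNAs use median normalization, equalizing per-sample nonzero medians at
their geometric mean. Counts enter the multivariate stages as
`log2(x + 1)`.

Methylation probes with **more than** 25% missing values are dropped
(strictly more: a probe missing in exactly a quarter of samples survives).
Remaining gaps are filled by feature-wise k-nearest-neighbour imputation
(`k = 10` by default): neighbours of a missing entry are features observed
at that sample, ranked by root-mean-square distance over co-observed
samples. Neighbours are features rather than samples because cohorts are
wide (many more probes than patients) and probe-probe correlation is the
stronger signal; the orientation and `k` are exposed in the API. Beta
values then become M-values, `log2((beta + offset) / (1 - beta + offset))`
with default offset 0 and beta clipped to `[1e-6, 1 - 1e-6]` — clipping
avoids infinities at the boundaries without perturbing mid-range values,
where an additive offset would.

## Sparse generalized CCA

Each block is divided by the square root of the leading eigenvalue of its
sample covariance, so blocks contribute by relative, not absolute,
variance. The fit then maximizes the centroid-scheme objective
$\sum_{j<k} c_{jk}\,\lvert\mathrm{cov}(X_j a_j, X_k a_k)\rvert$ under
$\lVert a_j\rVert_2 = 1$, $\lVert a_j\rVert_1 \le s_j \sqrt{p_j}$. The
absolute value admits negatively correlated pairs (methylation typically
anti-correlates with expression). Design weights $c_{jk}$ default to a
fully connected design (all off-diagonal 1) for the three blocks.

Numerics: weight vectors are initialized at each block's leading right
singular vector; each coordinate update soft-thresholds the gradient and
renormalizes, with the threshold found by bisection (100 iterations,
effectively machine precision); convergence is declared when the relative
objective change drops below `1e-8`, with a 1000-sweep cap; the objective
trace is stored and is non-decreasing by construction (each update
maximizes a linear minorant over the same constraint set). Components
beyond the first are fitted after deflating each block by regression on
its own component score. Sparsity is parameterized on (0, 1] with L1 bound
$s\sqrt{p}$ (floored at 1, since a unit-L2 vector has L1 norm at least 1),
matching the conventional 0.01–0.99 grid semantics.

Cross-validation fits a single component per fold with the candidate
sparsity on the block under selection and dense weights elsewhere, then
scores held-out samples by projecting them onto the training loadings.
AVE is implemented as **per-block AVE**: the mean squared Pearson
correlation between a block's variables and its component score. (Where a
per-block, inner, or outer variant is meant is often left implicit in the
literature; the per-block form is the one reported and labelled here.)
Selection uses a one-standard-error parsimony rule: among grid values
within one SE of the best mean AVE, take the fewest selected features,
ties toward smaller sparsity.

Because LASSO-style selection is unstable, features are stabilized by
refitting one component on 100 random half-samples and retaining features
with nonzero loadings in at least 70% of fits. The sparsity is held fixed
across subsamples (re-running CV inside every subsample would be
substantially costlier and changes the meaning of the selection frequency);
the retention rule is a weak inequality — 70/100 is kept, 69/100 is not.
The default component count is `min(5, n - 1)`, a desk-scale choice;
full-rank `n - 1` fits are configurable.

## Enrichment

Features map to genes (transcripts directly, CpGs via the probe-to-gene
map, possibly one-to-many, miRNAs via precursor tables); unmapped features
are reported, never dropped silently. Over-representation uses the
hypergeometric upper tail with Bonferroni adjustment (raw p times the
number of sets, capped at 1); category-versus-subtype association uses
Fisher's exact test. GSEA computes the classic weighted Kolmogorov–Smirnov
running sum (weight exponent 1) down a ranked transcript list with a
gene-label permutation p, `(1 + #{|ES*| >= |ES|}) / (B + 1)`. The ranking
statistic is a signed group-difference (mean difference over pooled s.d.)
between two sample groups from the metadata — the input ranking for a
"functions affected by differential expression" analysis is a genuinely
open choice, so it is configurable. Gene-label permutation was chosen over
phenotype permutation for determinism at desk scale. One degenerate case
is defined explicitly: a set covering the entire ranked list has no
misses, and its enrichment score is defined as 0.

## MI networks and threshold calibration

All MI estimation uses one estimator throughout — equal-frequency
discretization into `floor(sqrt(n))` bins and plug-in entropies, in nats —
so that thresholds calibrated on prior pairs are commensurable with the
candidate-edge MI they filter. ARACNE's data-processing inequality removes,
in every fully connected triangle, the weakest edge when it is strictly
below `(1 - epsilon)` times the smaller of the other two (default
`epsilon = 0`; an all-equal triangle is kept). All triangles are evaluated
against the original matrix, making the result order-independent, and
pruning is idempotent.

Thresholds come from known regulatory pairs: per edge type with at least
three prior pairs, the **median** prior-pair MI (medians, not means, so
outliers cannot dominate). The per-type MI distributions are compared with
all pairwise two-sample KS tests at a Bonferroni-corrected 0.05 (the
correction is a documented package choice); if none rejects, the scheme is
merged and the single global threshold is the lowest median — the
permissive choice that admits the most interactions. Candidate edges with
no type (no prior, no annotation support) are filtered at the lowest
per-type median for the same reason.

A function's subnetwork contains the stability-retained features annotated
to the function plus the retained features sharing a nonzero loading on the
same components ("covarying" is interpreted as shared-component membership;
a raw-correlation variant would be a straightforward alternative and the
node-selection step is isolated so it can be swapped). Edge types are
assigned from priors, probe-gene overlap, TF flags and miRNA target lists.

## Topology

Metrics follow NetworkAnalyzer/Cytoscape conventions on simple undirected
unweighted graphs: per-node average shortest path length over reachable
nodes; betweenness normalized by `(N-1)(N-2)/2`; closeness as reachable
count divided by summed distances; neighborhood connectivity as mean
neighbour degree; and the topological coefficient, for nodes of degree at
least 2, as the mean over nodes sharing a neighbour of (shared-neighbour
count, plus one if adjacent) divided by degree, else 0. Disconnected
graphs are handled per reachable set; isolated nodes are excluded from the
ASPL mean and contribute zero elsewhere. Network summaries are arithmetic
means over nodes; group summaries are unweighted means over networks
(each network counts once regardless of size). Reported tables round half
away from zero to 2–3 decimals.

## CpG classification and distances

Coordinates are internally 1-based closed (the GRanges convention); BED
input/output is 0-based half-open and converted at the boundary — one
convention, converted once, prevents off-by-one drift between UCSC-style
and Bioconductor-style sources. Promoters span 1,000 bp upstream of the
TSS through the TSS, strand-aware and clipped at position 1. A CpG
overlapping any promoter is a promoter; otherwise any enhancer overlap
makes it an enhancer; otherwise none. Promoter precedence when both
overlap is a documented tie-break, not an inference about intent.
Gene-CpG distances are absolute differences of interval midpoints, with
midpoints floored at half-integers.

## Cox screening

Features are standardized before interaction products are formed (products
of raw scales would conflate main effects and scale). The Breslow partial
likelihood is maximized by Newton–Raphson; ties are rare in synthetic data,
and Efron weighting is available as an option. Constant and collinear
columns are rejected up front with the offending columns named. P-values
are reported raw — the screening is per-model, mirroring common practice —
with an optional Benjamini–Hochberg column.

## The synthetic-data generator

The generator emulates: three sample-aligned blocks driven by sparse
shared latent factors (value = loading × factor + unit Gaussian noise,
loading magnitude = `factor_strength`, so two features loaded on one
factor correlate at `s²/(s²+1)`); monotone maps to the observed scales —
inverse-logit for beta values, negative-binomial counts with log-mean
proportional to the latent value (monotone maps preserve the MI ordering,
which is what threshold calibration relies on); planted typed regulatory
pairs carrying an extra pair-specific shared latent (default strength 3),
deliberately separate from the factors so that calibration has a signal
class of its own; missingness in the methylation block; toy genomic
annotation on a 20-kb gene grid with strand, promoter-window CpG placement
(default fraction 1, mirroring the all-promoter classification outcome the
pipeline reports on such data) and private enhancers for the remainder;
gene sets concentrated on factor-loaded genes plus random background sets;
and survival times from an exponential proportional-hazards model with
independent exponential censoring targeting 30%.

It does **not** emulate: 450K probe chemistry and array artifacts, batch
effects, GC/length bias, read-level sampling, realistic genomic geometry,
or correlated censoring. Passing recovery tests on this generator
demonstrates that the estimators see the structure they are designed for —
not that real cohorts satisfy these assumptions.

Default sizes used by the test suite and the acceptance script — cohorts of
60–200 samples with 30–150 features across blocks, 100 stability
iterations, 199–999 permutations — were chosen as the smallest scales at
which the recovery experiments are stable.

## Known limitations

- A single MI estimator is used everywhere; kernel or spline estimators
  would give different absolute MI values (the thresholds are only
  meaningful relative to the same estimator).
- Plug-in MI with `sqrt(n)` bins is biased upward at small n; calibration
  against prior pairs under the same estimator absorbs this bias, but
  absolute MI values should not be compared across sample sizes.
- Stability selection fixes the sparsity across subsamples.
- Only the centroid scheme is implemented; Horst/factorial schemes and
  supervised (outcome-guided) variants are out of scope.
- The Cox stage fits the terms it is given; it does not search model space.
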