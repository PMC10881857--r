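# omicnets

Semi-automated construction of functional regulatory network models from
matched multi-omic tumour profiles — DNA methylation (CpG beta values),
transcript counts and miRNA counts measured on the same patients, as in
TCGA-style lung adenocarcinoma / squamous-cell cohorts. The package is aimed
at computational biologists who want to go from three aligned omic matrices
to (i) a sparse, stable set of covarying features, (ii) function-level
enrichment of that set, (iii) mutual-information regulatory subnetworks per
enriched function with priors-calibrated edge thresholds, (iv) topology
summaries in NetworkAnalyzer conventions, (v) promoter/enhancer
classification of the CpG sites involved, and (vi) Cox screening of the
clinical relevance of the recovered gene interactions.

Every stage is runnable offline: a first-class synthetic-data module
generates three-block cohorts with known ground truth (sparse shared latent
factors, typed regulatory pairs, survival outcomes), so the whole pipeline is
testable end to end.

## Methods at the core

**Sparse generalized CCA (centroid scheme).** After eigenvalue scaling
(each block divided by the square root of its leading covariance
eigenvalue), block weight vectors `a_j` maximize

    sum_{j<k} c_jk | cov(X_j a_j, X_k a_k) |

subject to `||a_j||_2 = 1` and `||a_j||_1 <= s_j * sqrt(p_j)` with sparsity
`s_j` in (0, 1]. The absolute value (centroid scheme) lets negatively
correlated block pairs contribute. Optimization is block-coordinate ascent
with a soft-threshold L1/L2 projection; the objective is non-decreasing per
sweep. Sparsity is selected by k-fold cross-validation over a grid,
maximizing held-out AVE (mean squared variable–score correlation) with the
fewest features (one-standard-error rule), and feature sets are stabilized
by 100 half-sample refits, retaining features selected in at least 70% of
iterations.

**MI networks.** Plug-in mutual information on equal-frequency
discretizations (`floor(sqrt(n))` bins, nats), ARACNE's data-processing
inequality to prune the weakest edge of each triangle, and per-edge-type MI
thresholds set to the median MI of known regulatory pairs
(CpG–transcript, CpG–miRNA, TF–transcript, miRNA–transcript), merged to the
lowest median when Kolmogorov–Smirnov tests find no distributional
difference between types.

**Topology.** Per node: average shortest path length, betweenness
(normalized by `(N-1)(N-2)/2`), Cytoscape closeness (reachable count over
summed distances), neighborhood connectivity, topological coefficient; per
network and per network group: arithmetic means.

**Survival.** Breslow partial-likelihood Cox regression over standardized
features and their products (interaction terms), reported per term with
Wald tests.

## Worked example

```r
library(omicnets)
cfg <- pipeline_config(seed = 7, outdir = file.path(tempdir(), "demo"),
  synth = list(n_samples = 120, n_cpg = 40, n_transcript = 40, n_mirna = 20),
  sparsity = c(0.3, 0.3, 0.4), stability = list(n_iterations = 50))
res <- run_pipeline(cfg)

print(res$fit)
#> Sparse generalized CCA (centroid scheme)
#> blocks: cpg, transcript, mirna
#> components: 3; sparsity: 0.3, 0.3, 0.4
#> features selected (comp 1): 4, 4, 15
#> objective (comp 1): 2.22026 in 3 sweeps

print(res$stability)
#> stability selection: 14/100 features retained (>= 70% of 50 iterations)

print(res$threshold_scheme)
#> MI threshold scheme (per-type medians of prior-pair MI):
#>        cpg_mirna   cpg_transcript mirna_transcript    tf_transcript
#>           0.7348           0.7187           0.6919           0.5103
#> distributions indistinguishable (KS): merged, global threshold 0.5103

head(res$ora[, c("set", "overlap", "set_size", "p", "p_adj")], 1)
#>           set overlap set_size           p      p_adj
#> 3 FACTOR3_SET       4        4 0.002052765 0.04721359

print(res$topology)
#>       network     aspl         bc        cc      nc        tc
#> 1 FACTOR3_SET 2.472727 0.07417582 0.3336526 2.97619 0.1071429
```

Reading the output: the fit retains a handful of features per block at the
requested sparsity; stability selection keeps 14 of 100 features (these
include the planted factor loadings); threshold calibration finds the four
prior edge-type MI distributions indistinguishable and merges them at the
lowest median (0.51 nats); over-representation flags the gene set built
from the recovered factor (Bonferroni-adjusted p = 0.047); and the
function's MI subnetwork summarizes to a mean shortest path of 2.47 with
low betweenness, i.e. a loosely clustered module rather than a single hub.

Everything, including intermediate TSV/GMT/BED/SIF/GraphML artifacts and a
checksummed `manifest.json`, lands in `cfg$outdir`; a rerun with the same
config reproduces the stochastic stages byte for byte.

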