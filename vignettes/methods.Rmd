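---
title: "Methods: ensemble k-NN imputation and spatial pattern discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble k-NN imputation and spatial pattern discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `stens`, the
assumptions it rests on, the parameters that matter, the numerical and
design choices made where the method description left room, and what the
synthetic-data generator does and does not emulate.

## The imputation model

The data are a spatial *query* — an $m \times q$ cells-by-genes expression
matrix $Y$ plus 2-D cell coordinates — and one or more scRNA-seq
*references* covering a much larger gene set. Both are log-normalized
(per-cell totals, scale factor $10^4$, `log1p`). When the query and a
reference share only part of their panels, each cell's size factor is
computed on the shared genes so the two modalities sit on a comparable
scale, and the transform is then applied to all genes.

Each reference of $n$ cells is randomly partitioned into $\lceil n / n_0
\rceil$ equal-sized sub-references ($n_0 = 8000$ by default; the partition
is a seeded permutation, sizes differ by at most one). A sub-reference $X$
splits into the shared-gene block $X^{(1)}$ and the unique-gene block
$X^{(2)}$. For sub-reference $r$, similarity measure $t$ and neighbourhood
size $k$, query cell $i$'s prediction for unique gene $\ell$ is a weighted
average over its $k$ most similar reference cells on the shared panel,

$$\hat Y^{(2,rtk)}_{i\ell} =
  \frac{\sum_{j \in N_{rtk}(i)} w^{(rtk)}_{ij} X^{(2)}_{j\ell}}
       {\sum_{j \in N_{rtk}(i)} w^{(rtk)}_{ij}},$$

with ties in the neighbour ranking broken by ascending cell index, negative
similarities of signed (correlation-like) measures clamped to zero, and an
all-zero weight row falling back to the unweighted mean of the $k$
neighbours (this keeps the chosen neighbour set while avoiding 0/0).

Shared genes are predicted the same way (same neighbour sets). Averaging
those shared-gene predictions over all $(t, k)$ gives each sub-reference a
consensus self-prediction, and its *predictive power* is the squared
Pearson correlation with the measured values, pooling all cell-by-gene
entries: $s_r = \mathrm{cor}^2(\hat Y^{(1,r)}, Y^{(1)})$. Pooling entries
(rather than averaging per-gene correlations) is the literal reading of a
matrix-to-matrix correlation and weights abundant genes more; it is the
package's documented choice.

Weights are the min–max map of $s_r$ onto $[0.1, 0.9]$: the worst
sub-reference gets 0.1, the best 0.9, all-equal powers (including a single
sub-reference) get the midpoint 0.5. A fixed alternative that maps $[0,1]$
affinely onto the range regardless of the observed spread is available via
`impute_config(weight_map = "fixed")`; min–max is the default because the
stated range of weights is actually attained under it. The ensemble is

$$\hat Y^{(2)}_{i\ell} =
  \frac{\sum_r \sum_t \sum_k \omega_r \hat Y^{(2,rtk)}_{i\ell}}
       {|T||K| \sum_r \omega_r},$$

i.e. measures and $k$ values are treated as exchangeable and only the
sub-reference carries a weight. With exactly one sub-reference the weights
cancel and the ensemble is the plain average of the base predictions.
References need not share gene panels: a target gene is ensembled over the
sub-references that contain it, renormalizing by the weights of those
present.

**Assumptions.** The query is treated as the higher-fidelity modality:
predictive power is measured against the query's observations, so it can
only distinguish reference-quality differences that are large relative to
the query's own noise. When the query is as corrupted as the references,
$s_r$ saturates and can even favour references corrupted *like the query*;
that regime is outside the method's premise. Batch effects are not
corrected — the ensemble weighting is the mechanism that down-weights
references that transfer poorly.

### The ten similarity measures

Pearson, Spearman (average ranks for ties), cosine, Manhattan, Canberra
(0/0 terms contribute 0), Euclidean, the proportionality measures
$\rho_p(x,y) = 2\,\mathrm{cov}(x,y) / (\mathrm{var}\,x + \mathrm{var}\,y)$
and $\phi_s(x,y) = \mathrm{var}(x-y)/\mathrm{var}(x+y)$, a weighted rank
correlation, and the Jaccard index of supports. Distances pass through
$s = 1/(1+d)$ so that higher always means more similar. Two of these
required concrete choices the description leaves open:

* **Weighted rank correlation** — the weighted Pearson correlation of the
  two average-rank vectors with per-gene weights $w_g = r_g(x) + r_g(y)$
  (ascending ranks), so strongly expressed genes dominate. The weighting
  scheme is a documented default, not asserted as the only possibility.
* **Jaccard** — supports are taken at strictly positive expression; two
  empty supports have similarity 0.

Degenerate rows (zero variance under a correlation measure, zero norm under
cosine) get similarity 0 with a warning, so empty cells never become
preferential neighbours. The proportionality measures are computed directly
on the log-normalized vectors, which already live on a log scale, standing
in for the log-ratio transform of the original proportionality framework.

## Cross-validation and metrics

The shared panel is split into $N$ seeded folds of near-equal size (or one
fold per gene for leave-one-out); each fold is held out, predicted from the
remaining shared genes, and scored per gene by PCC, SCC and RMSE across
cells. Genes with zero variance in the measured values are flagged `NA`
rather than silently dropped. The accuracy ratio between two methods counts
strict per-gene wins over strict losses (ties in neither); a zero
denominator reports `Inf` together with the counts. A Wilcoxon rank-sum
helper is provided for reporting; it is not part of the method.

## Spatial pattern discovery

**Spatial weights.** A k-nearest-neighbour graph ($k_{spatial} = 6$) on the
cell coordinates, symmetrized by union. The operator the statistics use has
0.5 on the diagonal and neighbour weights summing to 0.5 per row.
Exact symmetry and exact row sums cannot coexist on an irregular graph, so
the package balances the adjacency by alternating row normalization with
symmetrization (a Sinkhorn-style iteration, tolerance $10^{-9}$, capped at
200 sweeps): the result is exactly symmetric with row sums equal to 1
within about $10^{-9}$ on spatial lattices. A Delaunay-based graph was
considered and rejected to keep FNN the only geometry dependency.

**Moran's I** uses the neighbour (off-diagonal) part of the operator, with
one-sided p-values for positive autocorrelation from the normal
approximation under randomization, BH-adjusted across genes. Spatially
variable genes additionally must be expressed in at least 5% of cells.

**SCI.** The spatial cross-correlation between two genes uses the *full*
operator including the self-loops,

$$\mathrm{SCI}(x,y) = \frac{n}{\sum_{ij} w_{ij}}
  \frac{\sum_{ij} w_{ij} (x_i - \bar x)(y_j - \bar y)}
       {\sqrt{\sum_i (x_i-\bar x)^2}\sqrt{\sum_i (y_i-\bar y)^2}},$$

so two genes expressed in the *same* cells score higher than two genes
expressed in adjacent cells — the property that lets a likelihood score
distinguish "same pattern" from "nearby pattern".

**Known patterns.** The genes-by-genes SCI matrix is thresholded at the
10th percentile of its off-diagonal values (inclusive, so a degenerate
all-equal matrix keeps every edge; values below the threshold become 0) and
the weighted network is clustered with Louvain at resolution 1, seeded.
Negative retained edges are clamped to zero for the modularity computation,
which requires non-negative weights. Single-gene patterns are dropped by
default (appropriate for larger panels; disable for very small ones). A
pattern's profile is the per-cell mean expression of its members.

**Likelihood scores and the dip gate.** Each predicted gene's likelihood
score is its maximum SCI against the known profiles. Hartigan's dip test on
the score distribution decides whether any predictions resemble no known
pattern: p ≥ 0.05 ends the search with "no novel patterns".

The dip statistic is implemented in the package (no suitable dependency was
available): the computation narrows a candidate modal interval while
charging the convexification/concavification deviations of the flanks —
the greatest-convex-minorant / least-concave-majorant scheme — in
"midpoint count" units where the lower bound $1/(2n)$ is exact. The
implementation was validated three ways: against an exact
linear-programming formulation of the unimodal-fit problem on random small
samples (agreement to $10^{-8}$; the LP oracle ships with the test suite),
against closed-form tie cases (equally spaced points give exactly
$1/(2n)$, balanced two-point clusters 1/4, three balanced clusters 1/6),
and by level/power simulation. The statistic is affine-invariant but *not*
invariant under general monotone transforms — it depends on spacings, not
only ranks. p-values are Monte-Carlo, simulated under the uniform null (the
asymptotically least favourable unimodal distribution), which controls the
test's level by construction.

**Classification.** A Gaussian KDE with Silverman bandwidth on 512 grid
points (the `stats::density` defaults) estimates the score density; the
split point $s$ is the density minimum between the two most *prominent*
local maxima. Prominence (height above the key saddle towards a taller
peak) rather than raw height is used because a ragged low mode can contain
the two tallest grid maxima, which would put the split inside one mode.
Scores above $s + 0.05$ join their best-matching known pattern (ties go to
the lowest pattern id; original profiles are kept for scoring, augmented
profiles are reported separately), scores below $s - 0.05$ are novel
candidates, the band between is "weak".

**Novel refinement.** Candidates lose their lowest decile by mean
expression, then their lowest decile by standardized dispersion; the
survivors' SCI network (same 10th-percentile rule) is clustered with
Louvain at resolution 0.6 (deliberately agglomerative, to avoid many small
clusters). A cluster is kept only if its mean within-cluster SCI exceeds
the mean of *all* pairwise candidate SCI scores by three standard
deviations — the reference distribution is global across candidates, the
package's documented scoping of an ambiguous rule. Within kept clusters,
genes with fewer than ten positive retained-network edges to other members
are removed iteratively until stable ("connections" counts positive edges:
negative SCI values are anti-associations and are never edges in the
clustering graph either). Representative genes of a pattern are the members
with the highest SCI to the pattern's own profile.

The three-standard-deviation rule is statistically demanding: it can only
pass when program cliques are a small fraction of all candidate pairs
(otherwise the cliques inflate the global standard deviation themselves)
and when Louvain leaves the cliques essentially pure (dilution lowers the
within-cluster mean quadratically). This is intrinsic to the rule, not an
implementation artefact, and shapes the study conditions below.

### HVG selection

Per-reference highly variable genes are ranked by variance standardized by
a mean-binned expected variance: genes are placed in equal-frequency bins
of mean expression (at most 20 bins, and at least ~20 genes per bin so a
bin cannot consist of variable genes alone) and each variance is divided by
its bin's median. The union of each reference's top 2000, minus the
measured panel, is the default prediction target set.

## The synthetic-data generator

`sim_spec()` describes a jittered-grid tissue with three gene classes:

* **Program genes** follow shared spatial profiles — smooth Gaussian bands
  across the tissue depth (layered, cortex-like) and/or sums of Gaussian
  hotspots (scattered). Known programs live in the measured panel (and
  partly in the unmeasured pool); novel programs live *only* in the
  unmeasured pool and are kept nearly orthogonal (profile correlation
  below 0.15) to everything else.
* **Background genes** ("singletons") are independent short-range smoothed
  random fields plus a weak shared long-range component that is
  orthogonalized against every program profile. They are spatially variable
  (they pass a Moran filter) and weakly mutually correlated — like the
  diffuse co-expression background of real tissue — but share no localized
  structure with any program. This class is what makes the
  three-standard-deviation rule meaningful: without it the global SCI
  spread is dominated by the planted cliques and the rule cannot pass at
  any threshold, and orphan background genes glue onto the strongest
  cliques during clustering.
* **Noise genes** are spatially unstructured positive values.

Per-gene target mean abundance is drawn independently of the spatial shape
(uniform on 0.25–0.6 log units), as in real panels where abundance and
pattern are unrelated; without this, the decile mean filter of the novel
refinement would systematically remove localized programs.

References resample cells with replacement from the noiseless expression
manifold and are corrupted per reference: multiplicative per-gene batch
factors (log-sd 0.1), additive Gaussian noise scaled by the reference's
quality multiplier, and Bernoulli dropout — all on the log scale, because
the pipeline consumes log-scale data (a raw-count path exists for I/O
tests). Query noise defaults to 0.3 log units; where tests exercise the
weight/accuracy relationship the query is set to imaging-grade noise (0.2)
with reference corruption graded up to σ = 2, since self-prediction against
a noisy query cannot resolve reference differences below the query's own
noise floor.

**What the generator does not emulate:** realistic count distributions
(negative-binomial sampling), segmentation errors, cell-type composition
shifts between query and reference, or spatially varying capture
efficiency. Passing tests therefore demonstrate the pipeline's mechanics
and calibration under controlled corruption, not performance on any real
tissue.

## Problem sizes and determinism

The test suite and the acceptance script run seeded simulations at desk
scale, chosen as the smallest sizes at which each claim is statistically
meaningful: 2000-cell queries with three graded references for the
ensemble-vs-base comparison; six graded references for the weight/accuracy
correlation; a 400-cell lattice and 500 permutations for the Moran null; a
30×30-cell tissue with 60 measured and 350 unmeasured genes (two planted
novel programs among a structured background) for pattern discovery; and
100 replicates for dip-test level and power. Every stochastic step takes an
explicit seed (`withr::with_seed`, never the global RNG state), so reruns
are bit-identical; reference partitioning, fold assignment, Louvain and the
dip-test null all derive from the caller's seed.

## Known limitations

* Predictive power saturates when the query is noisy; the weights then
  carry little signal (they stay in [0.1, 0.9] and never exclude a
  reference outright, which bounds the damage).
* The min–max weight map always uses the full range: with two nearly equal
  references one of them still gets 0.1. The `"fixed"` map avoids this at
  the cost of rarely reaching the endpoints.
* The dip gate tests the *score distribution*, not any specific gene: a few
  genuinely novel genes inside a broad unimodal score distribution will not
  trigger the search.
* The 10th-percentile network threshold retains 90% of all gene pairs; on
  small candidate sets the clustering therefore leans heavily on edge
  weights rather than topology.
* HDF5 round-trips write X transposed relative to the python convention
  and auto-detect orientation from the obs/var lengths, which is ambiguous
  for exactly square matrices.
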