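---
title: "Cluster markers and co-expression modules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster markers and co-expression modules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The two representations

A single-cell RNA-seq matrix can be summarized cell-wise or gene-wise.
The cell-wise (cluster) representation partitions cells into discrete
populations and characterizes each by marker genes that are
differentially expressed against all remaining cells. The gene-wise
(module) representation leaves cells intact and groups genes into
co-expression modules; each module's activity is then a per-cell score
(the module eigengene). The two views disagree exactly where biology is
interesting: programs that run at graded intensity across several cell
types, programs engaged by an experimental condition inside an otherwise
stable type, and rare programs active in a few percent of cells are all
real co-expression structure yet invisible to, or distorted by, a hard
partition of cells. `scmodules` implements both representations over one
`SingleCellExperiment` and the statistics that compare them.

# Preprocessing

Counts are normalized per cell to a fixed target total `s` (default
10,000, i.e. TP10K; `normalizeTotal()`), log-transformed as `log(1+x)`
(`logTransform()`), and the `n_top` most variable genes are flagged by
binned dispersion: genes are placed into 20 equal-count bins by mean log
expression and `ln(variance/mean)` is z-scored within each bin
(`selectHVGs()`). This realizes the standard mean–variance criterion; the
bin z-score prevents highly expressed genes from dominating purely
through their expression level. Ties are broken lexicographically by gene
id so selection is deterministic. Constant genes are never flagged.

Flagged genes are z-scored with the sample (n−1) standard deviation
(`scaleGenes()`); clipping of extreme values is available (`max_value`)
but off by default, since none of the downstream statistics require it.
PCA (`computePCA()`, default `d = 30`) is computed by SVD of the scaled
matrix, which is numerically equivalent to eigendecomposition of the
gene–gene covariance; the contract (eigenvalues, loadings, explained
variance) is stated on the covariance. Signs are fixed by making each
loading column's largest-magnitude entry positive, so results do not
depend on gene order or LAPACK conventions.

Clustering (`clusterLeiden()`) builds the exact k-nearest-neighbour graph
on the PCA scores (Euclidean, symmetrized by union, unit weights) and
runs Leiden under the modularity objective. The `seed` is mandatory —
Leiden refinement is stochastic — and labels are relabelled by
decreasing size from 0. Two practical notes: community granularity
scales with graph size, so on toy graphs of ~100 nodes the default
resolution 1.0 subdivides well-separated blobs (use a lower resolution
there), and the resolution → 0 limit yields a single community only for
connected graphs. Batch correction is a pluggable hook
(`correctBatch(sce, hook)`) applied to the PCA scores; the package ships
only the identity hook, so any external integration method can be
substituted without touching downstream code.

# Marker detection

`rankGenesOneVsRest()` tests each gene per cluster against all remaining
cells with the two-sided Wilcoxon rank-sum z statistic using the normal
approximation with tie correction and a 0.5 continuity correction.
The approximation is accurate in the intended regime (dozens of cells
per group and up); the test suite bounds its error against exact
enumeration on small groups at 0.05. BH adjustment is applied across
genes *within* each cluster comparison, matching the per-comparison
ranking semantics of marker detection. The log2 fold change uses a
pseudocount `eps = 1e-6`; means, fold changes and detection fractions are
computed on the log layer, consistent with the values the test ranks.
Detection fractions use a strict inequality (`> threshold`, default 0).

DEG sets (`topDEGSets()`, default top 100 per cluster with a
positive-fold-change filter) are ordered by ascending adjusted p, ties by
descending |log fold change|, then gene id. The Tau specificity index
(`tauScores()`) is

τ = Σᵢ (1 − xᵢ/x_max) / (n − 1)

over cluster means xᵢ; τ = 0 for uniform expression, 1 for expression
confined to one cluster, undefined (NA) when all means are zero. The
formula presumes non-negative xᵢ. Module eigengenes are signed, so for
eigengene input the per-feature minimum is subtracted when negative
before applying the formula; the returned vector carries a `"shifted"`
attribute to flag this. This shift is the minimal transformation that
makes the index well-defined without distorting the ordering of cluster
means; other choices (e.g. affine rescaling to [0,1]) would change τ's
value for partially specific modules.

`classifierValidation()` trains a seeded 500-tree Random Forest on the
DEG union and reports a row-normalized confusion matrix on an independent
dataset — the operational test of whether markers are transferable.

# Metacells and the co-expression network

Single-cell counts are too sparse for stable gene–gene correlations, so
`constructMetacells()` averages small groups of transcriptionally similar
cells: within each stratum (cluster × condition by default), seed cells
are sampled without replacement and joined with their k−1 nearest
neighbours in PCA space; candidates sharing more than `max_shared` cells
with an accepted metacell are rejected. Defaults (k = 25,
max_shared = 10, one metacell attempted per 3 stratum cells) follow
common practice at atlas scale; the package's own test fixtures use
k = 8, max_shared = 3, appropriate to their few hundred cells per
stratum. Mean aggregation operates on the log layer; `aggregation =
"sum"` on raw counts gives pseudobulk-style profiles instead.

`buildNetwork()` computes the correlation matrix (Pearson default;
Spearman and midweight bicorrelation available), raises |r| to the soft
power β (unsigned network), and forms the unsigned topological overlap

TOM_ij = (L_ij + a_ij) / (min(kᵢ, kⱼ) + 1 − a_ij),
L_ij = Σ_{u≠i,j} a_iu a_uj.

β can be fixed or chosen by `scanSoftPower()`: for each candidate the
connectivity distribution is binned (10 equal-width bins) and
log10(frequency) regressed on log10(k); the signed fit index is R² times
the negative sign of the slope, and the smallest β reaching 0.8 wins
(argmax as fallback, smaller β on ties). The typical useful range is
4–12; the package's fixture analyses fix β = 6, mid-range, because the
scan is itself sample-noise-sensitive at a few hundred metacells and a
fixed mid-range power makes the worked examples reproducible at a
glance. Gene count is guarded at 5,000 (`max_genes`) since the dense
TOM is quadratic in memory.

# Module detection

`cutModules()` clusters d = 1 − TOM by average linkage and extracts
modules with a bottom-up *locking* cut over the merge list:

1. a growing branch locks as a candidate module as soon as it reaches
   `min_module_size` genes (its locking height records its core
   cohesion);
2. genes that join a branch only after it locked fall into the grey
   pool — average linkage accretes unrelated genes onto tight branches
   near the top of the tree, and those accretions are not evidence of
   co-expression;
3. two locked branches that join close above their locking heights —
   relative gap (h_join − h_lock)/(1 − h_lock) ≤ `gap_frac` (default
   0.2) — are two halves of one module and merge; a high join keeps them
   separate.

A fixed-height cut was considered and rejected: on TOM dissimilarities
the background merges concentrate in a narrow band just below d = 1, so
every static height either returns giant mixed super-branches or
nothing, and no quantile choice is stable across datasets. The locking
cut is the essential behaviour of adaptive ("dynamic") tree cutting —
module boundaries decided branch-locally, a grey pool for unattached
genes — in a deterministic, dependency-free form.

Membership is then refined by eigengene connectivity: provisional
eigengenes are computed on the same matrix the network was built from,
members whose own-module kME falls below `kme_threshold` (default 0.30)
are demoted to grey, grey genes whose best kME reaches the threshold are
rescued into that module, and modules that fall under the size floor
dissolve. The demotion half of this rule is what keeps chance branches
of unrelated genes out of the module set: a random q-gene branch's
members correlate with its eigengene at roughly 1/√q plus sampling
noise, well under 0.30 for q ≥ 30 at realistic metacell counts, whereas
genuine module members sit far above it. Modules are named by the WGCNA
colour sequence in decreasing size order; `grey` is reserved for the
unassigned pool.

# Module statistics

`computeEigengenes()` standardizes each module's genes and takes the
first principal component of the submatrix, rescaled to unit variance.
The sign is fixed by requiring positive correlation with the module's
mean standardized expression, so "module up" always means "genes up";
PC1's sign is otherwise arbitrary and would flip between runs. kME
(`computeKME()`) is each gene's Pearson correlation with each eigengene,
computed on the single-cell log layer by convention (module definitions
come from metacells, hub inference from cells). Hub genes are the top
own-module kME members. `intermoduleCorrelation()` and
`differentialModuleExpression()` (Wilcoxon on eigengene values per group
pair, BH across modules within a pair — the same test family as the
marker track, applied to the module as the unit of analysis) quantify
program co-activation and condition responses.

One caveat worth knowing: library-size normalization couples genes
compositionally. When planted structured genes carry a large share of
total counts (≳30%), eigengenes of genuinely independent modules acquire
a visible negative correlation through the shared normalization factor.
Real transcriptomes keep any single program's count share far below
this, and the package's independence checks use background-dominated
compositions accordingly.

# Module preservation

`modulePreservation()` asks whether modules defined on a reference
dataset retain their structure in an independent test dataset. Observed
statistics per module: mean off-diagonal test adjacency among module
genes (density), and the correlation between members' within-module
connectivity vectors in reference versus test (connectivity pattern). A
permutation null draws `n_perm` (default 100) random gene sets of equal
size from the shared network genes; Z = (obs − null mean)/null sd per
statistic; Z_summary is their mean; the median rank (1 = most preserved)
is the median of the two per-statistic ranks, rounded to an integer.
Verdicts follow the conventional thresholds: > 10 strong, (2, 10]
moderate, ≤ 2 none, with the boundaries belonging to the lower category.

Two behaviours of this composite deserve note. With test = reference the
connectivity statistic is degenerate (observed and null are both exactly
1), so self-preservation rests entirely on density. And when structured
genes make up a large fraction of the network, random sets contain many
within-module pairs, inflating the null density — preservation Z-scores
are correspondingly conservative there. The package's reference check
therefore evaluates preservation between two *independent draws* of a
background-dominated generative model with strong planted modules
(within-module metacell correlation ≈ 0.75–0.8), where planted modules
score Z_summary ≈ 16–27 and random pseudo-modules score ≤ 2. Z-scores
are scale-invariant (correlations ignore multiplicative rescaling of the
test data), seeded, and deterministic.

# Comparison layer

`moduleDEGJaccard()` computes J = |∩|/|∪| between every cluster's DEG
set and every module's gene set — the direct bridge between the
representations. Jaccard (not a significance test) is used deliberately:
the aim is a descriptive, normalized overlap, not an enrichment p-value
biased by unbalanced set sizes. Across conditions,
`overlapCoefficientMatrix()` uses the Szymkiewicz–Simpson coefficient
|A∩B|/min(|A|,|B|), which saturates for nested sets — the right behaviour
when a program recurs in trimmed or extended form. Modules overlapping
at ≥ `threshold` (default 0.5) across conditions are consolidated into
core programs as connected components of the overlap graph
(`consolidatePrograms()`); raising the threshold can only split
programs. `hypergeometricEnrichment()` performs upper-tail
hypergeometric tests of gene sets against GMT annotation collections
with BH adjustment per query set and a user-controlled universe
(defaulting, in pipeline use, to the network genes) — a fully offline
replacement for web enrichment services.

# The synthetic generator

`simulateCounts()` draws counts from a negative binomial with
gene-shared dispersion θ = 2, per-gene log-normal baselines, and
per-cell log-normal library factors (σ = 0.3) — the minimal model with
scRNA-seq-like overdispersion and sparsity. Structure enters on the log
mean: cluster marker blocks add a fixed natural-log effect, and module
genes add w_j · z_im for a per-cell activity z and per-gene loading w,
so planted correlations survive the log1p transform approximately
linearly. Activities come in four flavours (shared, graded across
clusters, condition-shifted, and sparse/zero-inflated with Normal(3,1)
activity in a small cell fraction), and two modules can share a latent
factor to plant inter-module correlation. All randomness flows from one
seed and the global RNG state is restored afterwards.

`syntheticFixture()` is the package's reference scenario: 3,000 cells ×
1,200 genes, five clusters (proportions 0.30/0.25/0.20/0.15/0.10, 50
markers each at log-effect 3), three conditions, and six modules — one
conserved, one condition-responsive (mean shift +1 in the third
condition), one sparse (5% of cells), one graded (cluster means 0–1),
and a latent-factor pair whose "homeostatic" member is down-shifted by 1
in the perturbed condition. Module baselines are log-normal(log 2, 0.4)
— programs are detectably expressed — with loadings 0.4–0.75, except the
sparse module at 0.35–0.55. These values were chosen so the fixture
actually exhibits the phenomena the toolkit is about, with margins in
both directions: markers strong enough that Leiden recovers the planted
populations essentially exactly, module loadings strong enough for full
recovery by the network track, condition shifts moderate enough that
conditions shift programs rather than redefine cell types, and the
sparse program's loadings sitting in the window where it is invisible to
clustering (gene z-scoring amplifies rare bimodal signals, so this
window is real and not wide — push the loadings up ~50% and the 5%
active cells become their own Leiden cluster) yet clearly recovered as a
module through the binomial variation of active-cell counts across
metacells.

What the generator does *not* emulate: ambient RNA, doublets,
dissociation stress, batch chemistry differences, gene-length or GC
effects, and discreteness artifacts of very shallow sequencing. Passing
its tests shows the algorithms recover the statistical structures they
target at realistic noise levels — not that any particular biological
dataset contains them.

A note on null calibration: the no-structure calibration (zero non-grey
modules of size ≥ 30 on pure noise) constructs metacells in a single
stratum. Stratifying noise-data metacells by Leiden clusters *derived
from that same noise* is double dipping — genes whose fluctuations
defined the arbitrary clusters become correlated across metacell strata
and produce spurious modules. This is a genuine hazard of
cluster-stratified metacell pipelines on weakly structured data, worth
remembering when interpreting small modules on real datasets.

# Problem sizes and determinism

The shipped tests and the acceptance script run, by the package's own
choice, at desk scale: the reference fixture at 3,000 × 1,200,
preservation checks at 1,500 × 500 with 100 permutations, calibration
nulls at 3,000 × 400 over five seeds, and exhaustive oracles (TOM loops,
hypergeometric enumeration, exact rank-sum) at ≤ 30 genes or ≤ 12-gene
universes where enumeration is feasible. Every stochastic step — the
generator, Leiden, metacell seeding, Random Forest, permutation nulls —
takes an explicit seed, and re-running any stage with the same inputs
and seed reproduces its outputs bitwise.

# Known limitations

- Unsigned networks only; signed adjacency and signed-hybrid TOM are out
  of scope, so modules can mix positively and negatively correlated
  genes when |r| is high in both directions.
- No blockwise network construction: the full TOM is held densely, with
  a 5,000-gene guard.
- The preservation battery is the two-statistic composite described
  above, not the full WGCNA preservation suite.
- The exact-kNN searches are quadratic in cell number; at desk scale
  (≤ ~10⁴ cells) this is seconds, but atlas-scale data would need an
  approximate neighbour backend.
- Wilcoxon on single cells is anti-conservative under within-sample
  correlation; pseudobulk aggregation (available via `aggregation =
  "sum"`) is the conservative alternative for condition-level claims.
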