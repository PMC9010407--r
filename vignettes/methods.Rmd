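---
title: "Methods: clustering, label transfer, and annotation in scassign"
author: "scassign maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering, label transfer, and annotation in scassign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scassign)
```

# Scope

`scassign` is a headless toolkit for cell-type assignment in single-cell
data. It covers the standard path from a raw cell-by-feature count matrix
to annotated clusters — QC filtering, normalization, PCA/UMAP, kNN-graph
Leiden clustering, differential expression and gene-set
overrepresentation — plus three capabilities aimed specifically at
annotation across datasets and modalities: a frozen-cluster
semi-supervised variant of Leiden, reference-to-query label transfer with
confidence-based refinement, and projection of cluster assignments onto
spatial (e.g. multiplexed proteomics) cell centroids. This vignette
describes the models and the numerical choices behind each stage; the
README shows the workflows.

# Preprocessing

Cells are kept when their number of *expressed* features (strictly
positive counts) lies in `[min_genes_per_cell, max_genes_per_cell]`,
features when their number of expressing cells lies in
`[min_cells_per_gene, max_cells_per_gene]`; both bounds are inclusive,
reading "fewer than 50 or more than 3000" literally as strict exclusion.
The defaults (50 / 3000 on both axes) target experiment-scale droplet
data. Filtering is applied once, cells first and then genes, with no
iteration to a fixed point: gene filtering can in principle re-zero a
cell, but iterating the filters is a different (and less predictable)
contract, so the single-pass order is pinned.

Normalization scales each cell to a fixed total of `target_sum = 1e5`
counts and applies `log1p`; raw counts are retained in the `"counts"`
layer so differential expression and fold changes can reach back to them.
Scaling standardizes each feature to zero mean and *population* (ddof 0)
unit variance — the two conventions differ by `sqrt((n-1)/n)` and either
is defensible, so one is pinned and tested. Zero-variance features are
centred only. No post-scaling value clipping is applied (some toolchains
clip at 10; we do not, and this is deliberate and tested by the moment
checks). Spatial-proteomics intensities are used as measured: the
pipeline's bypass mode returns its input bit-identically.

# Dimensionality reduction and the neighbour graph

Clustering operates on a 40-component PCA of the scaled matrix
(`stats::prcomp`, exact SVD; with at most a few thousand cells the exact
decomposition is cheap, and it makes the embedding deterministic without
a seed). Components are ordered by explained variance. For
spatial-proteomics panels with tens of channels, a 10-dimensional UMAP
(`uwot`, single-threaded with `batch = TRUE` for seed-stable results) can
replace PCA as the clustering representation; a 2-D UMAP of the clustering
embedding serves visualization in either case. Precomputed reductions
(for instance a cell-by-topic matrix from chromatin topic modelling) are
accepted as CSV and used directly.

The kNN graph connects each cell to its `k_neighbors = 15` nearest
neighbours by Euclidean distance, self excluded; the directed lists are
symmetrized by union into an unweighted, undirected graph, so every node
has degree at least k. The search is exact: brute force with explicit
lowest-index tie-breaking below 2000 cells, a KD-tree (`FNN`) above.
Unweighted edges are pinned because no weighting scheme is part of the
contract, and unweighted graphs make the exhaustive-search oracle exact.

# Leiden clustering and the frozen-cluster variant

The quality function is RB-configuration modularity,

$$Q = \frac{1}{2m}\sum_c \left(2 e_c - \gamma \frac{K_c^2}{2m}\right),$$

with resolution $\gamma$ (default 1), $e_c$ the internal edge weight and
$K_c$ the summed degree of cluster $c$. The optimizer is our own Leiden
engine: queue-based local moving (only nodes whose neighbourhood changed
are revisited), greedy refinement that re-partitions each community from
singleton units, aggregation onto super-nodes, and an agglomerative
community-merge sweep that catches multi-node merges greedy single-node
moves cannot see. The whole pass repeats until quality stops improving.
Runs are restarted from randomized initial partitions (`n_restarts`,
default 5; raised to 20 on graphs of at most 32 nodes where local optima
are proportionally most harmful and restarts are nearly free), keeping
the best-quality result. All randomness flows through one explicit seed.

The semi-supervised variant constrains a partition rather than a seed
set: cells marked *frozen* keep their initial co-membership — frozen
cells sharing an initial label always end together, frozen cells with
different initial labels always end apart — while unfrozen cells move
freely, including into frozen communities. Mechanically, frozen nodes are
never enqueued for local moving, refinement treats each frozen group as
one indivisible unit, aggregation carries the frozen label onto
super-nodes, and the merge sweep refuses to join communities holding
different frozen labels. Because frozen groups start in distinct
communities and only unfrozen nodes ever move, the two constraint
conditions hold by construction on every path through the algorithm.

Correctness is validated against exhaustive enumeration: for a family of
graphs of at most 8 nodes (cliques, paths, cycles, stars, barbells, and
seeded random graphs) we enumerate every set partition (restricted-growth
strings; Bell(8) = 4140), filter to the constraint-satisfying ones, and
check that the engine attains exactly the maximal quality. The
`best_partition_exhaustive()` oracle is exported so users can rerun this
audit.

# scATAC gene activity

A peak-by-cell matrix with coordinate-encoded peak ids
(`chr1:100-200`, underscore and dash dialects accepted; coordinates
treated as 0-based half-open) is converted to cell-by-gene *activity*
scores by summing, per cell, the counts of every peak overlapping each
gene's extended span. Gene models come from a GTF (gene-level records,
GENCODE dialect; 1-based inclusive coordinates converted to 0-based
half-open). The span is extended 5000 bp downstream and 1000 bp upstream
of the gene, strand-aware, so "downstream" means past the 3' end; this
asymmetric, 3'-heavy extension is applied literally as stated, and a
`strand_aware = FALSE` switch applies the two extensions in coordinate
order instead. Overlap means at least 1 bp on half-open intervals; a
peak overlapping several extended genes contributes its full count to
each (no fractional weighting), and genes with no overlapping peak are
retained as all-zero columns so the gene universe is stable. Counts, not
binarized accessibility, are summed. Chromosome-name harmonization
("1" vs "chr1") happens only on request, never silently; a total absence
of overlaps combined with disjoint chromosome names produces a diagnostic
suggesting it. The interval search runs on `GenomicRanges`; tests compare
it against a brute-force double loop over all (peak, gene) pairs on 100
randomized fixtures with deliberate boundary placements (peaks abutting
an extended edge on either side, minus-strand genes, clipping at zero).

# Label transfer and refinement

Transfer fits a latent space on the reference only: the gene intersection
with the query is taken in reference feature order, the reference
restricted and standardized, and a PCA with up to 40 components fit.
Query cells are standardized **with the reference means and standard
deviations** and projected through the reference-fit rotation — scaling
the query by its own statistics is rejected because it breaks the
self-transfer identity (query = reference must reproduce the reference
embedding exactly; we test this to 1e-8). Each query cell takes the
majority label among its k = 15 nearest reference cells, ties broken by
summed inverse distance and then by the smaller label. The per-cell
confidence is the fraction of neighbours voting for the winner.

Refinement freezes trusted clusters and re-clusters the rest:
`select_frozen_clusters()` freezes every cell of clusters whose median
confidence reaches a threshold (default 0.9), or an explicit cluster-id
list — the analyst's-choice path, which mirrors how trusted clusters are
selected by inspection in practice. `transfer_and_refine()` then runs
semi-supervised Leiden on the query's own kNN graph (built on the
query's own scaled PCA, not the reference projection), initialized from
the transferred labels.

`transfer_experiment()` packages the benchmark on synthetic data:
transfer, refinement, and reference-free de novo Leiden are each scored
against the query's ground truth by ARI. The generator
(`make_transfer_pair`) builds the three difficulties this workflow is
designed for. First, a *sibling family*: three of five types share a
common marker program and differ in small private blocks that the query
batch attenuates, so de novo clustering of the query merges the family
while the reference projection — where the distinction is intact —
separates it. Second, *concentrated annotation noise*: the corrupted
fraction of reference labels fills up from the abundant highest-index
type, mostly mislabelled as the adjacent type, so neighbour voting merges
the two noisy types at low confidence while clean types stay confident.
Third, a mild per-gene batch shift. Refinement wins by both mechanisms
at once: frozen sibling clusters cannot merge (the separation constraint),
and the unfrozen noisy merged cluster is split back into its two types by
the query graph. The experiment freezes the sibling clusters through the
override path: their vote confidences are structurally capped near 0.7 by
sibling vote-splitting, so a confidence threshold cannot identify them —
the same reason trusted-cluster choice is an expert judgement in real
analyses. Under the default conditions (30% corrupted labels, 20 seeds)
the mean ARIs order as refined > transferred > de novo with wide margins.
Uniform iid label noise cannot produce this ordering at all: voting
corrects it and unconstrained refinement then converges to the same graph
optimum de novo clustering finds. The concentrated-noise design is
therefore not incidental; it is the regime in which semi-supervised
refinement has value.

For joint multimodal data measured on the same cells,
`copy_labels_by_cell_id()` transfers labels by shared cell identifier,
assigning an explicit `"unassigned"` to unmatched cells and warning
(not failing) on zero matches.

# Differential expression and enrichment

Markers are found by Welch's unequal-variance t-test per gene, cluster
versus rest, computed on normalized log values *before* unit-variance
scaling — a zero-mean scaled matrix is degenerate for fold-change
computation. Sample (ddof 1) variances, Welch–Satterthwaite degrees of
freedom, two-sided p, Benjamini–Hochberg adjustment across genes. Genes
whose statistic is undefined (fewer than two observations a side, or zero
pooled variance with unequal means) are reported with `NaN` and excluded
from adjustment and ranking. The log2 fold change de-logs the means with
a pseudocount of 1: `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`.
`top_markers()` takes the 500 largest fold changes (signed by default —
markers are conventionally up-regulated — with an `absolute` switch),
ties broken by smaller p then gene id; when fewer genes exist, as with a
19-channel protein panel, all are returned.

Gene-set analysis is a hypergeometric overrepresentation test of the
marker list against GMT collections: one-sided tail probability of at
least the observed overlap given query size, term size, and a
user-supplied background universe, BH-adjusted across terms. The
weighted running-sum enrichment statistic used by GSEA-style tools is a
deliberate non-goal: the overrepresentation test consumes the same
inputs, serves the same ranking purpose, and is exactly checkable
against direct probability-mass summation.

# Spatial projection

Cluster assignments are drawn side by side: the 2-D expression embedding
on the left, per-cell spatial centroids on the right, both coloured by
one deterministic HCL palette keyed on cluster ids — identical partition,
identical colours, which is the property that makes the panels readable
together and is asserted structurally in tests (plus a pixel probe that
finds every cluster colour in both panels). Spatial coordinates follow
the microscopy convention: origin top-left, y increasing downward (the
spatial panel reverses the y axis). Segmentation is upstream: the package
consumes precomputed centroids from CSV.

# Synthetic data

All tests and the acceptance script run on synthetic data from the
`fixtures` generators, which are pure functions of a `FixtureSpec`
(seed included). `make_counts()` draws negative-binomial counts
(dispersion 0.5, so `size = 2`) over lognormal base means centred at 0.5
counts — sparse, as droplet data is — with each planted type
up-regulating its own 10% block of marker genes 4-fold, then applies 30%
uniform dropout. Defaults are 300 cells, 2000 genes, 5 types; at these
settings the full pipeline recovers the planted partition essentially
perfectly, and smaller or flatter configurations are used in tests where
failure modes are the point. The transfer pair is described above; the
spatial fixture places each type as a Gaussian blob (sd 40 px) on a
1000 x 1000 px tile with centres on a circle of radius 350 px, pairwise
at least 300 px apart for up to 7 types.

What these generators do *not* emulate: per-cell library-size variation
beyond what NB sampling induces, gene–gene correlation structure within
programs, ambient RNA, doublets, batch effects richer than a per-gene
multiplicative shift, or realistic spatial tissue architecture. Passing
tests on these fixtures therefore demonstrate algorithmic correctness
under the stated model — exact agreement with enumeration and
brute-force oracles, planted-structure recovery, contract compliance —
not performance claims on real tissue.

# Numerical choices and degenerate inputs

- Ambiguous on-disk orientation (square matrix, equal sidecar lengths)
  is an error unless the caller states the orientation; duplicated cell
  or feature ids are rejected, never merged.
- Sparse backing is chosen automatically below 50% density; all
  operations are tested to give identical results for sparse and dense
  backing within 1e-10.
- Quality comparisons inside the Leiden engine use a 1e-12 improvement
  margin so float noise cannot masquerade as progress; acceptance
  comparisons against enumeration use 1e-9.
- kNN ties at equal distance resolve to the lower cell index; vote ties
  resolve by inverse distance then smaller label. With a fixed seed every
  stage, including UMAP, is byte-reproducible, and the command-line
  interface derives all stage seeds from one run seed.
- Problem sizes in the test-suite and acceptance runs (300-cell
  fixtures, 20 replicate seeds, 100 randomized overlap fixtures,
  exhaustive search up to 8 nodes) were chosen so each check is decisive
  for the property it tests while the whole suite stays fast enough to
  run on every change.

# Known limitations

The Leiden engine is written in R and comfortable up to a few thousand
cells — the regime of the bundled experiments; beyond that, the
per-node loops dominate and a compiled implementation would be the next
step. Approximate nearest-neighbour backends are permitted by the kNN
contract (99% edge agreement with exact search) but not shipped; the
exact search is used throughout. The hypergeometric test treats the
background size as given rather than deriving it from an expression
universe. Confidence-threshold cluster freezing keys on neighbour-vote
agreement, which underestimates trust for types with close siblings and
overestimates it under systematically consistent annotation errors — the
override path exists precisely for those cases.
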