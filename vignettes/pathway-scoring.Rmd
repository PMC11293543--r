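---
title: "Per-cell pathway scoring: model, protocol, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-cell pathway scoring: model, protocol, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipsic)
```

## The scoring model

Single-cell RNA-seq matrices are dominated by zeros: most genes are
captured in only a minority of cells, and per-gene expression estimates in
any single cell are noisy. `sipsic` summarizes the activity of a gene set
(pathway) in each cell by combining all of the set's genes, normalized so
that they contribute on comparable scales and weighted so that the genes
measured most reliably contribute most.

Given a genes × cells matrix $X$ on linear scale (TPM or CPM) and a gene
set with $n$ members present in the matrix, the score of cell $j$ is built
in two steps.

**Step 1 — robust per-gene normalization.** For each gene $i$, take the
$\tau\%$ of cells with highest expression (default $\tau = 5\%$; window
size $k = \max(1, \lceil \tau n_{\text{cells}}/100 \rceil)$) and let
$NF_i$ be the median of those top values. Because the data are sparse,
this median is usually positive but — unlike a maximum — not an outlier.
When the median is zero (genes expressed in under $\tau/2\%$ of cells),
the gene's maximum is used instead. The normalized gene score is
$S_{ij} = X_{ij} / NF_i$; an all-zero gene has $NF_i = 0$ and its row of
$S$ is defined as zero.

**Step 2 — rank-weighted aggregation.** Genes of the set are ranked by
their total expression across all cells, midranks on ties, so that the
highest total receives rank $n$. The pathway score of cell $j$ is

$$P_j = \frac{1}{n^2} \sum_{i=1}^{n} \mathrm{rank}_i \, S_{ij}.$$

Highly expressed genes are detected in more cells and their profiles carry
more information; the rank weighting lets them dominate the score while
never discarding the low-expression genes entirely.

### The denominator choice

The weights $\mathrm{rank}_i / n^2$ sum to $n(n+1)/(2n^2) \approx 1/2$,
not to 1, so $P_j$ as printed is about half of a true weighted average of
the $S_{ij}$. `score_pathway()` implements the $1/n^2$ form as the
default and offers `denominator = "weighted_mean"` ($n(n+1)/2$, weights
summing to one). The two differ by a per-pathway positive constant, so
every downstream quantity that compares cells within a pathway —
t-statistics, FDRs, Z-scores, cell orderings, clusterings — is identical
under either choice; a test asserts this invariance.

### Numerical conventions

* Window size rounds up and is floored at one (`top_tau_count()`), so the
  top-$\tau\%$ window is never empty even for groups of a handful of
  cells. The rounding convention matters only for tiny matrices.
* The median of an even-sized window is the mean of the two central order
  statistics (R's default).
* Ties in total expression get midranks, which makes scores independent
  of the order in which genes are listed.
* Zero-coverage sets raise an error in `score_pathway()` and are skipped
  with a warning (and recorded in metadata) in `score_collection()`.
* Scores on nonnegative input are nonnegative and finite; sparse and
  dense representations agree to machine precision.

## Preprocessing protocol

`preprocess_matrix()` applies, in fixed order: de-log (only for matrices
declared `unit = "log"`), a cell filter, a gene filter, and CPM
normalization (only for raw counts):

* **Cell filter.** Cells expressing fewer than 1000 genes (at least one
  read) are removed; exactly 1000 is kept. The threshold suits droplet
  and Smart-seq data with genome-wide gene panels; for the synthetic
  matrices below (1000 genes total) the validation harness uses
  `min_genes = 100`.
* **Gene filter.** Genes expressed in less than 10% of the *remaining*
  cells are removed; exactly 10% is kept. Order matters and is fixed:
  cells first, then genes.
* **CPM.** Each count is divided by its cell's total and multiplied by
  one million, after filtering. Matrices already in TPM/CPM are left
  untouched.
* **De-log.** Published log-scale matrices are converted back to linear
  scale with `base^x - pseudocount` (clipped at zero). The base and
  pseudocount of a published matrix are often unstated; the default
  `log2(x + 1)` is the dominant convention and both parameters are
  exposed.

Scoring a matrix still tagged as log-scale warns rather than errors:
the scores are then rank-weighted sums of normalized *log* expressions,
which compress fold changes but are not meaningless.

## Differential pathway analysis

`pairwise_analysis()` implements the group-comparison protocol:

* an unpaired two-sided **Student's t-test** (pooled variance) per
  pathway per group pair. "Student" is taken literally; Welch is
  available via `var_equal = FALSE` for strongly heteroskedastic groups.
* **Benjamini–Hochberg** adjustment across all pathways *within one
  pairwise comparison*. The FDR family choice matters when more than two
  groups exist; adjusting per pair (then aggregating) is the only reading
  under which per-pair FDRs exist before the maximum is taken. BH itself
  is an assumption — no specific FDR procedure is canonical for this
  protocol — and is stated here prominently.
* the **max-FDR rule**: a pathway is called *up* in a focal group only if
  its median difference is positive against every other group and the
  largest of its pairwise FDRs is below the threshold (default 0.01);
  *down* symmetrically; otherwise *ns*. Direction comes from median
  differences, not the t-statistic's sign, making calls robust to a few
  extreme cells.

With two groups the procedure reduces exactly to one t-test per pathway
plus BH. Degenerate inputs are handled explicitly: two constant groups
with equal means give $t = 0, p = 1$; with unequal means the test is
undefined and errors rather than returning a misleading zero p-value.

## Pathway-space representation

`zscore()` standardizes each pathway row ($n-1$ denominator; constant
rows become zero and are flagged). `heatmap_order()` reproduces the
standard layout for differential-pathway heatmaps: within each group,
cells sorted ascending by mean Z-score over that group's upregulated
pathways; pathway blocks per group, sorted by ascending max-FDR.

`cluster_cells()` fixes a clustering contract rather than a library:
standardize, build a symmetric k-nearest-neighbour graph (Euclidean
distances in pathway-Z space, default 20 neighbours), and partition with
Louvain at resolution 0.5. Pathway space has at most as many dimensions
as pathways (50 for the hallmark collection), so no PCA step precedes the
graph. The kNN graph is unweighted and symmetrized by edge union; shared
neighbour (SNN/Jaccard) pruning as performed by some toolkits is
deliberately not imitated, since its parameters are not part of the
contract. `embed_cells()` runs UMAP on the same representation,
single-threaded and seeded. Determinism is a contract on one platform and
library version, not across versions.

The kNN construction materializes the full distance matrix and is
intended for the tens of thousands of cells typical of one dataset, not
for atlas-scale inputs.

## The synthetic-data generator

`simulate_counts()` draws counts i.i.d. from a negative binomial with
mean 2 and dispersion (size) 1 per gene and cell, multiplies the mean by
a pathway's fold change for planted genes in the affected group, applies
independent Bernoulli dropout with probability 0.7, and finally adds any
batch offsets. The defaults — 1000 genes, two groups of 100 cells, 50
disjoint 20-gene pathways — give overall sparsity around 80%, comparable
to droplet data, while keeping a full pipeline replicate under a second.
`standard_recovery_spec()` fixes the reference scenario used by the
validation harness: five pathways upregulated threefold in each of the
two groups, forty null.

What the generator does *not* emulate: library-size variation between
cells, gene-specific means and dispersions, correlated gene modules
within a pathway, and mean-dependent dropout. Consequently, passing
recovery tests demonstrates that the scoring and calling machinery
detects planted mean shifts under heavy sparsity; it does not certify
performance on real data, where between-gene heterogeneity is the main
additional difficulty. Batch offsets are additive constants on the counts
of non-pathway genes for a cell subset — a deliberately crude patient
artifact that perturbs gene space strongly while leaving pathway scores
nearly untouched, which is exactly the contrast the pathway-space
clustering experiment needs.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* agreement of the vectorized scorer with a naive loop reference on 200
  random matrices (≤ 20 genes × 10 cells);
* exactness of a hand-computed 2-gene × 3-cell example;
* normalization edge rules and per-gene scale invariance (100 random
  cases);
* null calibration — 50 null pathways × 100 replicates at 100 cells per
  group, call rate at FDR < 0.01 (observed well under 2%) — and power 1.0
  over 50 replicates for a threefold 20-gene shift at dropout 0.7;
* direction-call agreement across $\tau \in \{2, 5, 10\}\%$ on the
  standard recovery scenario (≥ 90% of pathways agree; 5% remains the
  default as the intermediate choice);
* recovery of three planted functional groups (adjusted Rand ≥ 0.9)
  by pathway-space clustering on 300 cells with patient-specific offsets
  on non-pathway genes, with no cluster dominated by a single patient —
  each group's program spans 8 of the 50 pathways, reflecting that
  cell-state programs touch many pathways at once;
* byte-identical outputs under a fixed seed, and scoring of a 5000-gene ×
  10,000-cell sparse matrix against 50 pathways in seconds.

## Known limitations

* Gene sets must be single-direction; sets mixing up- and downregulated
  members should be split before scoring, and the package provides no
  bidirectional mode.
* Scores depend on the cell population through $NF_i$ and the ranks:
  adding or removing cells changes all scores slightly. Scores are
  comparable within one matrix, not across independently scored
  matrices.
* The FDR-family and BH choices above are assumptions where the protocol
  is underdetermined; both are isolated behind `pairwise_analysis()`.
* Gene identifiers match exactly and case-sensitively; `read_gmt(...,
  uppercase = TRUE)` is the only folding offered.
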