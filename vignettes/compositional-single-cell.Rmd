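---
title: "Compositional log-ratio analysis of sparse single-cell counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional log-ratio analysis of sparse single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codasc)
```

## The model

A sequencer caps the total number of reads per cell, so a single-cell
RNA-seq profile carries only relative information: if one transcript takes
more of the budget, every other transcript takes less. Formally the counts
$x_{1j}, \dots, x_{Dj}$ of cell $j$ are a composition — only the ratios
$x_{ij}/x_{kj}$ are meaningful — and compositions live on a simplex, not in
Euclidean space. Standard downstream tools (PCA, k-means, trajectory
inference) assume Euclidean geometry, so compositional analysis first maps
each cell through a log-ratio transformation:

* **CLR** (centered log-ratio): $\mathrm{clr}(x)_i = \log x_i - \frac1D
  \sum_k \log x_k$, the log of each part over the geometric mean of all
  parts. Columns sum to zero.
* **ILR** (isometric log-ratio, pivot coordinates): $D-1$ orthonormal
  contrasts $\sqrt{\tfrac{D-i}{D-i+1}}\,\log\!\big(x_i \big/
  (\prod_{k>i} x_k)^{1/(D-i)}\big)$. Distances equal CLR distances
  (`ilr()` and `clr()` norms agree per cell, tested to 1e-8).
* **HKGLR**: log-ratio against the geometric mean of a housekeeping panel
  (default *SDHA, ACTB, UBC, YWHAZ, GAPDH*), a knowledge-based denominator.

The obstacle is sparsity: 70–95% of entries are zero (true absence or
technical dropout) and $\log 0$ is undefined.

## Count-addition schemes

`addition_scheme()` adds a strictly positive per-cell offset $\delta_j$
before closure. Constant offsets (1, 0.01, 0.0001) are classical but treat
a cell sequenced to 500 counts and one sequenced to 50,000 identically, and
they demonstrably distort the geometry of sparse matrices (the constant
schemes are the weakest performers in the package's own directional
benchmark). The depth-aware schemes set $\delta_j$ proportional to the
cell total $S_j$:

| kind | $\delta_j$ | note |
|------|-----------|------|
| `S10000` | $S_j/10^4$ | the offset implicit in log-normalization |
| `SMAX` | $S_j/\max_k S_k$ | largest offset exactly 1 |
| `SGM` | $S_j/\mathrm{GM}_k(S_k)$ | geometric mean of offsets exactly 1 |
| `HALFMIN` | half the cell's smallest positive count, zeros only | kept for completeness; performs poorly on sparse data and is not recommended |

`SGM` is the recommended default: it is self-calibrating (no magic 10,000)
and scales to future, deeper experiments.

Geometric means are always computed as $\exp(\mathrm{mean}(\log\cdot))$;
products overflow at $D \approx 20{,}000$. All logarithms are natural —
the log-normalization bridge below requires one consistent base.

## The log-normalization bridge

Log-normalized data, $\log(x_{ij}\,s/S_j + 1)$ with scale factor
$s = 10^4$, equals $\log(x_{ij} + S_j/s) + \log(s/S_j)$. The second term
is constant within a cell, so centering each column by its mean recovers
the CLR of the `S10000` scheme *exactly*. `clr_from_lognorm()` implements
this; the equivalence against the independent count-addition path is
asserted elementwise to 1e-10 on random sparse matrices. Practical
consequence: public datasets distributed only in log-normalized form can be
moved into the compositional framework without raw counts.

## Numerical and design choices

* **Sparsity-aware CLR.** All zeros of a cell share the value
  $\log\delta_j$, so the per-cell log-geometric-mean costs $O(\mathrm{nnz}
  + N)$ and a gene-restricted output (`genes_out`) never materializes the
  dense $D \times N$ matrix (instrumented memory test). Offsets are stored,
  never added into the sparse matrix.
* **CLR denominator on subsets** always uses *all* $D$ genes, matching the
  derivation of the bridge above. Some ecosystems center on the subset;
  that choice breaks the equivalence and is deliberately not offered.
* **Scale invariance** holds exactly for `S10000` under uniform count
  scaling and for `CONSTANT` when the constant is scaled with the counts.
  For `SMAX`/`SGM` the offsets are *ratios* of totals and do not scale
  with a uniform rescaling of counts, so exact invariance cannot and does
  not hold for them; their virtue is depth-adaptivity, not this identity.
* **ILR gene order** is input order (pivot coordinates). Permuting genes
  changes individual coordinates but no distances or norms (tested).
* **Truncated SVD.** `pca_truncated()` removes per-gene means and runs
  implicitly restarted Lanczos bidiagonalization (irlba). The exact
  full-SVD route `lra_exact()` is retained as an oracle; scores agree with
  it to |cosine| > 0.999 per component on test fixtures. SVD sign
  ambiguity is resolved by forcing each component's largest-magnitude
  loading positive, making embeddings bit-reproducible for a seed.
* **QC.** Cells under 200 detected genes are dropped, then 3-MAD outliers
  on log1p totals, log1p detected genes (two-sided) and percent
  mitochondrial counts (upper side). The covariates are standard; the
  3-MAD rule is fixed here because no threshold is canonical, and it is
  configurable. Order is cells first, then genes detected in fewer than 10
  cells — the order changes results and is pinned by test.
* **HVG selection** ranks per-gene variance *of the representation being
  analyzed* (CLR pipelines select on CLR variance), with deterministic
  lexicographic tie-breaks. A shared LogNorm-based selection can be passed
  explicitly when head-to-head fairness across methods matters.
* **Clustering** delegates to seeded k-means (10 restarts) by default.
  The graph route uses shared-nearest-neighbour Walktrap cut at exactly
  $K$ communities: Louvain cannot be cut at a prescribed $K$, and the
  evaluation protocol fixes $K$ to the number of known labels.

## Evaluation statistics

For partitions: entropy of accuracy $H_{acc}$ (mean within-cluster entropy
of true-group composition, divided by the number of clusters $M$), entropy
of purity $H_{pur}$ (the mirror), ARI, and NMI ($2I/(H+H)$, natural log).
Lower entropies and higher ARI/NMI are better. One caveat found while
testing: the bound $H_{acc} \le \log M$ only holds when $M \ge N$ (true
groups); the unconditional bound is $\log N$. The standard protocol sets
$M = N$, where both coincide. For trajectories: Spearman correlation of
pseudotime with true time; a pairwise ordering score (+1/−1/0 per
comparable pair — the endpoints ±1 and the all-tied 0 are the analytically
forced values, and the pairwise form is our operationalization of the
published ordering-score idea); and branch matching by largest overlap
with the true branches, reporting overlap rate, trajectory false rate, and
incorrect cell-type proportion. For biomarkers: rank-based (Mann–Whitney)
AUROC per gene, distribution-free by construction, with panel summaries of
the fraction of genes above AUROC cutoffs and a known-non-marker panel for
false-positive estimation. `baseline_delta()` reports every method
relative to the log-normalization baseline with signs oriented so positive
is always better.

## What the simulator emulates — and what it does not

`simulate_counts()` generates gamma-Poisson grouped data in the style of
the Splatter simulator at its default hyperparameters: gene base means
$\mathrm{Gamma}(0.6, 0.3)$, library sizes $\mathrm{LogNormal}(11, 0.2)$,
each group perturbing a random 10% of genes by $\mathrm{LogNormal}(0.1,
0.4)$ factors (direction equiprobable), Poisson emission, and logistic
dropout $P(\text{drop}) = \mathrm{plogis}(\text{shape}\cdot(\log(\mu+1) -
\text{midpoint}))$ with shape −1, midpoint 0, applied to observed counts
so the pre-dropout matrix is exactly recoverable. It does **not** model
over-dispersion beyond gamma-mixing of means across genes (no per-entry
BCV layer), batch effects, doublets, or gene-gene correlation beyond group
structure — so a green directional test says the methods behave as claimed
*under this generative model*, not that they will on any real dataset.

For the desk-scale directional benchmark (2000 genes × 600 cells) the
library-size location is set to 7.7 rather than 11: the default is
calibrated for 10,000 genes, and holding it while cutting genes five-fold
produces an implausibly deep matrix (~25–36% zeros) on which every method
saturates. At 7.7 the matrix has ~67% zeros and ~2,200 counts per cell —
typical good-quality droplet data. This was fixed once, before the
directional thresholds were evaluated.

`spike_degraded()` emulates low-quality cells: copies of a target
population with a fresh random 60% of genes zeroed, appended as
`"<type>-zero"` cells. The evaluation embeds and clusters the *full*
spiked dataset with $K$ equal to the number of labels in the spiked
annotation, then scores the ARI on the target + degraded subset: the
failure mode of log-normalization is scattering degraded cells across
unrelated clusters (where they can masquerade as transitional states),
which only a full-dataset clustering can expose.

## Known limitations

* ILR and HKGLR build a dense log matrix of all genes; they are intended
  for post-QC/HVG matrices, not raw 20,000-gene matrices with millions of
  cells. CLR is the scalable route.
* Outputs are 64-bit; R has no native 32-bit float matrix, so the
  half-size disk option is not provided.
* The ordering score is single-lineage; multi-branch pseudotime is scored
  per branch after `match_branches()`.
* Imputation (MAGIC/ALRA) and SCTransform are out of scope: their outputs
  can be fed in as matrices and passed through `clr_from_lognorm()`.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_counts(sim_params(n_genes = 2000, n_cells = 600,
                                  libsize_logmean = 7.7, seed = 1))
truth <- setNames(as.character(sim$truth$group), sim$counts$cell_ids)
res <- run_pipeline(run_config(sim$counts, transform = "clr",
                               scheme = addition_scheme("SGM"),
                               qc = NULL, truth_labels = truth, seed = 1))
res$metrics
base <- run_pipeline(run_config(sim$counts, transform = "lognorm",
                                qc = NULL, truth_labels = truth, seed = 1))
baseline_delta(res$metrics, base$metrics)
```
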