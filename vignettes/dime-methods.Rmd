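---
title: "Mapping disease genes onto immune cell types: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disease genes onto immune cell types: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Curated disease-gene associations say *which* genes are linked to a disease
but not *where* those genes act. For immune-mediated inflammatory diseases a
natural "where" is the immune cell type. `dime` answers that question by
mapping each disease's associated genes (DAGs) onto a reference expression
matrix of immune cell types — an *immunome*: genes in rows, cell types in
columns, values on the log2(CPM + 1) scale, one column per cell type
(median over its samples) — and extracting the cell types (DACs) and genes
that dominate the expression pattern.

## The model

For a disease $D$ with gene set $G_D$, the immunome rows for $G_D$ form the
matrix $X_D$ (genes $\times$ cell types). $X_D$ is factorised by
non-negative matrix factorization,

$$X_D \approx W_D H_D = \sum_{i=1}^{k} w_{i} h_{i},$$

where $W_D \ge 0$ is genes $\times k$ and $H_D \ge 0$ is $k \times$ cells.
The factorization minimises the generalized Kullback–Leibler divergence

$$D(X \,\|\, WH) = \sum_{ij} \Big[ X_{ij} \log \tfrac{X_{ij}}{(WH)_{ij}}
  - X_{ij} + (WH)_{ij} \Big]$$

by the classical multiplicative updates, which decrease the objective
monotonically. Each of the $k$ rank-one components $w_i h_i$ is a *cluster*
pairing genes (weights in $w_i$, the $i$-th column of $W_D$) with the cell
types that express them (weights in $h_i$, the $i$-th row of $H_D$).

Within each cluster, $h_i$ and $w_i$ are scaled to $[0, 1]$ by division by
their maximum — so zero weight keeps meaning "no contribution", unlike
min–max scaling — giving the DAC and DAG scores. Members at or above the
75th percentile of their cluster's scores (linear interpolation between
order statistics, R's type-7 quantile) are the *top* DACs/DAGs; the maximum
always qualifies, so top sets are never empty. Clusters are ranked by the
Frobenius norm of their rank-one component, computed through the identity
$\|w h\|_F = \|w\|_2 \|h\|_2$; the largest is the *top cluster*. The
bipartite *DIME network* of the disease is the union over clusters of the
complete bipartite products (top DACs) $\times$ (top DAGs), tagged by
cluster rank.

### Choosing k

For every candidate $k$ (2 up to 7, capped at one less than the smaller
matrix dimension) the factorization is restarted 30 times from seeded
uniform initialisations. Each restart yields a binary cell–cell
connectivity matrix (two cells connected iff they share the argmax cluster
of their $H$ column, ties to the lowest index); the restart average is the
consensus matrix. Stability is the Pearson correlation between the
consensus distances $1 - \bar{C}$ and the cophenetic distances of
average-linkage hierarchical clustering on them (the cophenetic
correlation coefficient; defined as 1 when the distances are constant). The
smallest $k$ attaining the maximum coefficient is selected. The original
description of this criterion leaves the exact rule open ("where the
coefficient begins to fall" versus "maximum"); we use
maximum-with-smallest-k tie-break and expose the full $(k, \rho)$ table in
every result and run manifest.

### Numerical choices

* Initialisation: $W, H \sim U(0,1)$ scaled by $\sqrt{\overline{X}}$, one
  seed per restart, derived deterministically from the caller's seed.
* Stopping: relative divergence decrease below $10^{-6}$ over a
  10-iteration window (with a small additive floor so the rule remains
  meaningful when the divergence approaches zero), capped at 2000
  iterations. Factors are floored at $\varepsilon = 10^{-12}$, which also
  guards the divisions inside the updates.
* Consensus restarts additionally stop once the cluster assignment has been
  unchanged for 40 consecutive iterations — the classical stopping rule of
  consensus NMF clustering. Only the connectivity matrix is consumed from
  those runs; the factorization that is *scored* is re-fitted at the chosen
  $k$ under the full divergence rule, keeping the best (lowest final
  divergence) of 30 restarts. Scores therefore always come from a single,
  fully converged factorization.
* Ties in cluster ranking keep the lower original cluster index first; ties
  in cell assignment go to the lowest cluster index.
* A gene or cell may be a top member of several clusters; edges record the
  cluster rank, and nothing forces cluster-exclusive membership.
* At least 15 mappable disease genes are required to attempt a
  factorization (`min_genes`); unmappable genes are counted and reported,
  never silently dropped.

## Preprocessing and filtering

When raw counts are supplied: genes with fewer than `min_count = 20` reads
in at least `sample_fraction = 0.95` of samples are removed (the boundary
counts as removal; both knobs are configurable), counts become
log2(CPM + 1), and samples collapse to cell-type medians (midpoint
convention for even sample numbers). Disease-gene tables are filtered by
removing HLA genes — by the case-insensitive symbol prefix `HLA-`, the
reproducible reading of "HLA-associated", with an optional explicit
exclusion list — because their constitutive expression in myeloid and B
cells would bias every disease toward those lineages; the remaining genes
are intersected with the immunome on exact symbols (no alias mapping), and
the dropped count is reported.

## Stability: jackknife resampling

Each disease's result is stress-tested by re-running the entire procedure
(including re-selection of $k$, the conservative reading of "re-run the
analysis") on random subsamples: `n_sim = 1000` simulations by default,
each drawing 70% of the disease's genes (to test cell stability) or 70% of
the cell types (to test gene stability, tracking the original run's top-10
genes by score — mirroring the asymmetric convention of the original
description). Occurrences as a top member of the *top* cluster are counted;
the verdict is a two-sided Pearson correlation test between original
top-cluster scores and counts, significant at $p \le 0.05$. Simulation $s$
uses seed $\texttt{base\_seed} + s$, so results are exactly reproducible; a
complete subsample (frac = 1) reproduces the original run. Zero-variance
count vectors leave the correlation undefined and the verdict
non-significant, with a warning.

## Comparing diseases

Two diseases are compared through their networks' $(cell, gene)$ edge sets:
the intersection is the *common cell-gene network*, the Jaccard index
measures overlap, and a one-sided (enrichment) Fisher's exact test — the
upper hypergeometric tail — gives its significance. The original
description states neither the test's sidedness nor its universe;
"confidence p-value for the given overlap" reads as over-representation,
so one-sided. The universe defaults to $|\text{cells}| \times
|\bigcup_D G_D|$ for edge comparisons and to the loaded gene universe for
plain gene-set comparisons; both are configurable and recorded in the
output, since absolute p-values depend on them. No multiple-testing
correction is applied (matching the stars-on-raw-p presentation this
method family uses); the long-form table carries raw p-values so users can
adjust.

Druggable genes (present in a drug-gene interaction table, optionally
restricted to approved drugs) are decorations on the networks — annotation
never changes edges or scores. Repurposing candidates are the druggable
genes appearing in significant (p ≤ 0.05) common networks, ranked by the
number of diseases they connect; a strict flag marks genes that are top
DAGs of the rank-1 cluster in *every* listed disease.

## The synthetic study conditions

Real inputs (a GEO-derived immunome, a DisGeNet snapshot, DGIdb/CLUE/hPDI
tables) are point-in-time artifacts, so validation uses a planted-module
generator. Its defaults are the package's study conditions:

* 300 genes $\times$ 40 cell types, values $\max(0, N(\mu, 0.5))$ on the
  log2(CPM + 1) scale, background $\mu = 1$;
* module 1: 75 genes at $\mu = 7$ in 10 primary cells (a high/low gap of 6
  at noise sd 0.5) and $\mu = 3$ in 10 secondary cells;
* module 2: 75 genes at $\mu = 6$ in 10 different primary cells, $\mu =
  2.5$ in the remaining 10 cells.

Module genes are 25% of genes and primary cells 25% of cell types, so the
top-quartile membership rule makes "recovered exactly the planted members"
the attainable optimum and precision/recall against planted truth
well-posed. The secondary tier emulates related immune lineages sharing a
programme at lower level; it also gives every cell type a stable cluster
home — with a flat background block, cells with no signal have no
well-defined assignment, which destabilises the consensus at the true $k$
and pushes the cophenetic criterion toward spurious extra clusters. The
two modules differ in mean (7 vs 6) so that cluster ranking, and hence
"the top cluster", is well-defined rather than a coin flip.

What the generator does *not* emulate: correlated immune-lineage structure,
count-level noise (a Poisson count mode exists for exercising the
preprocessing path, not for benchmarking recovery), gene-gene correlation,
and annotation errors in disease-gene tables. Passing the planted-recovery
tests therefore demonstrates algorithmic correctness under clean block
structure, not performance on real immunomes.

Validation sizes are chosen to exercise the method at full default
parameters while remaining quick: 20 replicate seeds for recovery, 200
jackknife simulations (the tool's default for real analyses remains 1000),
and three-disease comparison scenarios at 400 genes.

## Known limitations

* NMF is a non-convex optimisation; best-of-30-restarts makes results
  reproducible and usually stable, but not globally optimal.
* The cophenetic criterion can prefer fine splits when expression blocks
  are themselves structured; the per-run $(k, \rho)$ table is always
  retained so the choice can be audited.
* Absolute Fisher p-values depend on the universe convention (reported in
  every output) and carry no multiplicity correction.
* Gene symbols are opaque strings; cross-nomenclature mapping is out of
  scope and mismatches simply reduce the mappable gene count, which is
  logged.
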