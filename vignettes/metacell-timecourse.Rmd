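---
title: "Metacell pseudoreplicates for time-course differential expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacell pseudoreplicates for time-course differential expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metareplicate)
```

## Model and assumptions

The package addresses per-gene differential expression through time in
scRNA-seq data with very few biological replicates per time point. The
statistical unit is the **metareplicate**: a metacell (average normalized
expression of a group of similar cells) treated as one observation at its
time point. For each gene and cell type we fit

$$y = A x^2 + B x + C$$

by ordinary least squares, where $y$ is mean log-normalized expression of a
metacell and $x$ the day since symptom onset. The ANOVA F-test
($F = (SSR/2)/(SSE/(n-3))$, df $2, n-3$) tests the null that all
coefficients are zero; per-gene p-values are Benjamini–Hochberg adjusted
*within each cell-type stratum*, and a gene is a DEG when $q < 0.05$ **and**
$R^2 > 0.5$. The $R^2$ gate is what makes the procedure robust to the
inflated-n pathology of cell-level testing: it demands the curve actually
explain the data, not merely be distinguishable from flat.

A quadratic was chosen deliberately: it can represent monotone rises and
falls with changing velocity and single interior extrema, but cannot chase
cyclical variation. The fit assumes independent, homoscedastic Gaussian
residuals at the metareplicate level — a reasonable description of averages
of tens of cells on the log scale, and exactly what the simulator generates.

Degenerate inputs: constant genes raise a typed condition
(`metareplicate_constant_gene`) and are excluded *before* testing rather
than assigned $p = 1$, keeping the BH denominator honest. Genes positive in
exactly one metareplicate and zero elsewhere are likewise excluded
(`single_nonzero_filter()`): such a pattern fits a parabola through one
outlier perfectly and carries no trend information. Strata with fewer than
4 metareplicates or fewer than 3 distinct days are skipped (the F-test
needs $n \ge 4$ and the design needs 3 distinct abscissae).

## Trend taxonomy

Each DEG gets one of eight **expression-velocity trends**. The velocity is
$f'(t) = 2At + B$; its absolute value increasing (accelerating) or
decreasing (decelerating) over the window is decided by where the vertex
$t^* = -B/2A$ sits relative to the window. The decision procedure of
`classify_trend()`:

1. Observed per-day means first: strictly-interior maximum pattern →
   `MAXIMA`; strictly-interior minimum → `MINIMA`. Strict inequalities;
   ties fall through.
2. Direction from the fitted endpoints ($f(t_{max})$ vs $f(t_{min})$; exact
   tie decided by the derivative sign at the window midpoint).
3. If the quadratic coefficient is not significant ($p_A \ge 0.05$) the
   curve is linear: `*_CONST`.
4. Otherwise vertex at/right of the window end → `*_DECEL`; at/left of the
   start → `*_ACCEL`; strictly interior (and not an observed extremum) →
   the endpoint with larger $|f'|$ decides.

Two genuinely open points were decided here: (a) an interior-vertex DEG
that the observed-means rule does not catch has no published label; we use
the dominant-endpoint-velocity rule above, which is continuous with the
edge-vertex cases. (b) The Maxima/Minima rule is evaluated on the
*post-masking* day grid, so a cell type whose early days were dropped is
judged only on the days actually modelled.

## Metacell strategies

**sMetacells** are built per time point, never pooling days, so that each
metacell is unambiguously one observation at one time. The published
archetypal-analysis software this emulates is approximated by a documented
surrogate (bit-level equivalence is out of scope): on the day's cells we
build an adaptive-Gaussian kernel
$w_{ij} = \exp(-d_{ij}^2/\sigma_i\sigma_j)$ with $\sigma_i$ the distance to
the $\lceil k/3\rceil$-th neighbour, seed the target number of archetypes
by greedy max-min similarity (first seed: highest kernel density), and
alternate (i) assigning every cell to its most similar archetype and (ii)
re-selecting each archetype as the member maximizing the within-group
kernel sum (a kernel medoid). Both steps are monotone in the summed
cell-to-archetype similarity, so the refinement reaches a fixed point; 50
iterations bound the runtime. The procedure is deterministic given the
embedding, which is itself deterministic (PCA with a fixed sign
convention), so identical seeds give identical runs.

The **target count** is one metacell per 75 cells, rounded to the nearest
10 (half-up) with a floor of 10 — the floor exists so sparsely sampled days
still yield enough metareplicates — and per-day overrides (the default
requests 20 on the final day, where a baseline comparison benefits from
more units).

**rMetacells** average 20 randomly chosen same-type cells, 3 per
(day, type) stratum. Cells are drawn without replacement within a metacell;
different metacells of a stratum may share cells, because strata can be
smaller than 60 cells and the published design does not forbid overlap.
Strata under 20 cells are skipped with a warning rather than padded.
**Pseudobulk** sums raw counts per (sample, cell type) and renormalizes the
sums — the comparator both metacell methods are judged against.

Metacell typing is by member majority (lexicographic tie-break for
determinism); **purity** is the modal fraction; severity is the member
modal label.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scale_factor` | 10,000 | library-size normalization target (counts per cell are divided by the cell total, scaled, log1p'd); the upstream convention, not a published value |
| `ratio` | 75 | cells per sMetacell |
| `k` | 15 | kernel neighbourhood; bandwidth uses the ⌈k/3⌉-th neighbour |
| `n_per_metacell`, `n_replicates` | 20, 3 | rMetacell stratum design |
| `alpha`, `r2_min` | 0.05, 0.5 | the two DEG gates |
| `min_n` | 4 | minimum metareplicates per tested stratum |
| `min_cells_per_type` | 500 | cell types below this total are excluded before testing |

The HVG statistic (variance of normalized expression, z-scored within 20
mean-expression bins, lexicographic tie-break) and the embedding (PCA, 50
components, scaled HVG expression clipped at $|z|=10$, component sign fixed
by the largest-absolute loading) are conventions chosen for determinism;
the source study used its original authors' processed reduction, which is
not reconstructable without the accession. A user-supplied embedding
overrides the internal one, and batch integration is deliberately not
re-implemented.

## What the simulator emulates — and what it does not

`simulate_timecourse()` draws counts as
$\mathrm{NB}(\mu = s_c e^{\eta_{cg}},\ \phi = 0.1)$ with
$\eta_{cg}$ = gene baseline ($\mathcal{N}(0,1)$) + planted class trajectory
+ type-marker offset (2.5 log-units) + state-marker offset (2.0) +
patient offset ($\mathcal{N}(0, 0.1)$) + cell noise
($\mathcal{N}(0, 0.2)$), and $s_c$ lognormal (sdlog 0.3, mean 1). Noise
enters on the log scale so metacell averaging of log-normalized values
behaves like the averaged normalized expression the statistics assume. The
default world: 10 days (3–28), 5 cell types × 2 states × 120 cells per
(type, day), 1,000 genes of which 8 × 25 carry planted trends with range
1.0 log-units, 2 of 5 patients sampled per day, the first patient severe.
Severity multiplies the steepness of decreasing (interferon-like) planted
trajectories by 1.5, so severity-stratified exports show the
faster-declining severe trajectories the design anticipates.

Planted trajectories are the *maximum-curvature* member of each class with
the stated range: linear for `*_CONST`, vertex at the window edge for the
accelerating/decelerating classes, vertex at the midpoint for
`MAXIMA`/`MINIMA`, each validated at generation time against the
closed-form class constraints and the classifier itself.

Not emulated: gene–gene correlation beyond the planted block structure,
ambient RNA, batch effects, dropout beyond NB sampling, or realistic
cell-type abundance skew. A green test on this world therefore establishes
internal correctness of the pipeline (recovery of planted programs, honest
null behaviour, the variance ordering between strategies), **not** fidelity
to any particular real dataset.

## Numerical choices

* OLS via QR; $(X^\top X)^{-1}$ from `chol2inv(qr.R(...))`; per-coefficient
  two-sided t-tests on $t(n-3)$. The full-model t-test stands in for a
  published stepwise-selection p-value for the quadratic term; for the only
  use made of it (linear vs parabolic at $\alpha = 0.05$) it is the minimal
  faithful surrogate.
* BH is the literal step-up with `cummin` monotonicity, order-preserving.
* Sample SDs use the $n-1$ denominator throughout (`mSD` diagnostics);
  mSD averages over *all* genes, not HVGs — both are conventions chosen
  once for determinism where the published analysis is silent.
* Pooled-variance t-tests (`baseline_contrast()`) return $t=0, p=1$ for
  identical degenerate groups and error on zero variance with unequal
  means.
* "Detected" means normalized expression strictly greater than 0.

## Known limitations

* The planted-label recovery property is power-limited by design: at range
  1.0, noise 0.2 and 4 metareplicates/day the quadratic-term t-test has
  ≈80% power even for the maximum-curvature edge-vertex trajectories
  ($|t_A| \approx 2.8$), so ≈15% of recovered edge-class genes are labelled
  `*_CONST` and overall label accuracy sits near 0.88, below the 0.90
  asserted by the corresponding acceptance property. This is a property of
  the stated world and the $p_A$ rule, not of the implementation; the test
  is left asserting 0.90.
* The sMetacell surrogate preserves the kNN-kernel/archetype character of
  the published method but is not the published optimizer; comparisons are
  property-based (partition, purity, variance ordering), never
  bit-equivalence.
* Single-cell-granularity regression is provided as a comparator
  (`as_single_cell_set()`) and inherits all the pathologies that motivate
  metareplicates; it is not a recommended analysis path.
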