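# metareplicate

Metacell pseudoreplicates for time-series single-cell differential
expression.

## The problem

Time-series scRNA-seq studies of, e.g., PBMCs after viral infection usually
carry only 1–3 biological samples per time point. That is too few replicates
for bulk time-course statistics, while treating each of thousands of cells
as an independent observation grossly inflates test statistics (huge n,
tiny per-cell information, FDR-significant genes whose fits explain almost
nothing). `metareplicate` implements a middle path: aggregate each time
point's cells into **metacells** — groups of transcriptomically similar
cells whose normalized expression is averaged — and treat those metacells
as replicates ("metareplicates") in a per-gene quadratic regression over
time.

Two metacell strategies are compared against pseudobulk:

* **sMetacells** (`construct_smetacells()`): a kernel-archetype procedure on
  an adaptive-Gaussian kNN kernel (greedy max-min seeding + assignment /
  kernel-medoid refinement) that deliberately spreads metacells across the
  cell-state space of each time point, preserving within-type heterogeneity
  and hence realistic between-replicate variance.
* **rMetacells** (`construct_rmetacells()`): averages of 20 randomly drawn
  same-type cells — a baseline that underestimates variance because random
  draws concentrate in the densest state.
* **pseudobulk** (`aggregate_pseudobulk()`): summed counts per
  (sample, cell type), renormalized.

## The statistic

For each gene and cell type, with metacell expression `y` and day `x`:

```
y = A x^2 + B x + C
```

fit by OLS; the ANOVA F-statistic `F = (SSR/2)/(SSE/(n-3))` tests the null
that all coefficients are zero; p-values are BH-adjusted within the cell
type and genes pass with **FDR < 0.05 and R² > 0.5**. Each DEG is then
assigned one of eight **expression velocity trends** from the sign of its
fitted direction, the significance of the quadratic term (p_A), the vertex
position of the parabola, and the observed per-day means (Maxima/Minima
rule): Increasing/Decreasing × {constant, ↑ velocity, ↓ velocity}, plus
Maxima and Minima.

A seeded negative-binomial simulator (`simulate_timecourse()`) plants all
eight trend shapes in a configurable multi-type, multi-state, multi-patient
time course so the full pipeline is testable without any external dataset.

## Worked example

```r
library(metareplicate)

cfg <- run_config(seed = 1,
                  sim = list(n_cell_types = 3, cells_per_type_day = 40,
                             n_genes = 240, n_de_per_trend = 4,
                             type_marker_n = 12, state_marker_n = 8),
                  min_cells_per_type = 100, k = 10)
run_pipeline(cfg, "out")
```

prints (log excerpt):

```
[simulate] 1200 cells x 240 genes simulated (seed 1)
[preprocess] 240 HVGs, 50 components
[metacells] smetacells: 110 units
[metacells] rmetacells: 90 units
[metacells] pseudobulk: 60 units
[filter] 110 -> 110 sMetacells after type/day filters
[degs] 720 fits, 14 per-type DEGs; 1 all-cells DEGs
[trends] trends assigned (DEC_ACCEL=3, DEC_CONST=3, INC_ACCEL=2, INC_CONST=2, MINIMA=4)
[diagnostics] variance + detection diagnostics written
```

Reading: 1,200 simulated cells over the default 10-day grid were aggregated
into 110 sMetacells (10 per day, 20 on day 28), 90 rMetacells and 60
pseudobulk units; 720 per-(gene, type) quadratic fits yielded 14 DEGs
passing both gates, each labelled with its velocity trend; pooling all
metacells regardless of type leaves a single globally changing gene —
the expected behaviour when type-specific programs dilute each other.
Outputs land as TSVs in `out/` (`degs_per_type.tsv`,
`variance_per_stratum.tsv`, `severity_expression.tsv`, ...), with the
resolved config in `out/config.json`.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/metareplicate.R run-all --seed 1 --out out/
Rscript inst/cli/metareplicate.R simulate --seed 7 --out sim/
```

On structured simulations the variance diagnostics reproduce the motivating
ordering — e.g. at the default stated world, grand-mean mSD (mean per-gene
SD across a stratum's metareplicates) is ~0.46 for sMetacells vs ~0.17 for
rMetacells, with pooled-across-days sMetacell mSD within 2× of pooled
pseudobulk.

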