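---
title: "Methods: single-cell heterogeneity analysis of cultured MSCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell heterogeneity analysis of cultured MSCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscpop)
```

`mscpop` analyses droplet scRNA-seq UMI counts from cultured mesenchymal
stromal cell (MSC) populations, where the dominant sources of variation are
typically the cell cycle (these are highly proliferative cultures) and
donor-to-donor batch effects, and the biology of interest — candidate
subpopulations with different differentiation propensities — sits beneath
them. This vignette explains each stage's model and assumptions, the
parameters that matter, the design choices that were genuinely open, and
what the simulation-based tests do and do not establish.

## Quality control

Cells are filtered per donor on three metrics: `log(total UMI)` (lower
tail), `log(detected genes)` (lower tail) and mitochondrial UMI fraction
(upper tail), each at 3 MADs from the donor median with the 1.4826
consistency factor, removing the union of flags. The MAD rule assumes each
donor's bulk of cells is homogeneous on the log scale; the tails tested are
the standard directions for low-quality cells (debris/empty droplets are
shallow; dying cells are mito-rich). The sides and the mito gene
identification (`MT-` prefix by default) are exposed because conventions
differ across references.

Degenerate inputs: zero-total cells are excluded from the MAD fit and
always removed; a zero MAD with non-constant input flags every off-median
value on the tested side (with a warning); donors with fewer than 3 cells
are skipped. Re-running the filter re-estimates the thresholds on the
surviving cells and may remove more; passing the previous report's
`bounds` freezes the thresholds and makes filtering idempotent.

Genes with mean UMI below 0.1 across the pooled donors are then removed; a
mean of exactly 0.1 is retained (the removal rule is strictly "less
than").

## Normalization

Two normalizations serve different purposes:

* `lognormalize()`: `ln(1 + 10^4 x / total)`. Used for module scores,
  marker detection and potency, where per-gene interpretability and fold
  changes matter. Natural log and scale factor 10⁴ follow the common
  single-cell convention.
* `nb_regularized_residuals()`: per gene, a negative-binomial regression
  of counts on `log10(total)` (log link, intercept + slope) with
  dispersion θ estimated by method-of-moments and refined by maximum
  likelihood (`MASS::theta.ml`); genes detected in fewer than 5 cells are
  carried as zero residuals. The per-gene parameters are then regularized
  across genes by **local-linear** Gaussian kernel regression over
  `log10(gene mean)` (bandwidth 3 × the Silverman rule-of-thumb value,
  evaluated on a 200-point grid and interpolated). Local-linear smoothing
  matters: the intercept-vs-mean curve is close to linear and a
  local-constant smoother leaves design and boundary bias that shows up
  directly as miscalibrated residual means. Raw parameter estimates that
  are gross outliers against a first-pass smooth (beyond 5 robust SDs and
  1 unit) are excluded from the regression — a single aberrant count can
  otherwise drag a gene's own fit to reproduce the outlier — and those
  genes receive values from the final curve like everyone else. Residuals
  `(x − μ)/sqrt(μ + μ²/θ)` are clipped at `±sqrt(n_cells)` so no single
  cell dominates downstream PCA.

The residual model assumes counts for a gene are NB given depth within a
homogeneous population; on Poisson-simulated data (post gene filter,
2,000 cells) the per-gene residual means are below 0.05 in absolute value
and the median per-gene variance is within [0.8, 1.2].

## Cell-cycle scoring

`module_score()` compares a gene set's mean log-normalized expression per
cell with an expression-matched control: all genes are cut into 24
equal-frequency bins of average expression, and for each target gene 100
control genes are sampled (seeded, without replacement, capped at the bin
size) from its bin. The control profile averages each target gene's own
bin sample, so bins contribute in exactly the proportions of the target
set — a flat union of controls would re-weight bins by size and bias the
null score. Scores are invariant to adding a constant to every value, and
a background-like set scores ≈ 0.

Phase assignment: G1 when both scores ≤ 0, otherwise the larger of S and
G2M, with exact positive ties broken to G2M (a measure-zero event,
documented for determinism). The shipped 43-gene S and 54-gene G2/M human
program lists (`inst/extdata/cc_genes_*.txt`) are editable text; results
are reported for whatever lists are supplied.

## Consensus highly variable genes

Within each donor and assigned phase (groups under 10 cells are skipped),
genes are ranked by variance standardized against a loess trend (span 0.3)
of `log10(variance)` on `log10(mean)` of the raw counts, with standardized
values clipped at `sqrt(n)`; the top 2000 per group are kept. Phase sets
are intersected within a donor — a gene variable in every phase is
variable for reasons other than the cycle — and donor sets are then
combined by union (the default; intersection is available via
`across_rule`). Union is the default because donor-private biology is
real signal, while the per-donor phase intersection already guards against
cycle-driven variability.

## Confound regression, PCA, SNN, Louvain

Residuals restricted to the consensus HVGs are regressed per gene on
(s_score, g2m_score, donor indicators) by OLS; residuals are z-scored and
clipped at ±10. Collinear covariate columns are dropped with a warning;
regression residuals are orthogonal to every covariate at machine
precision. PCA is a plain SVD of the centered matrix (20 PCs by default).

The SNN graph uses neighbor sets of self plus the k = 20 nearest cells in
PC space (distance ties broken by cell index), Jaccard edge weights, and
pruning at 1/15. Louvain is implemented directly (local moving passes in
seeded random order, then graph aggregation, repeated until modularity
stops improving) with a resolution parameter γ in the modularity
`Q = Σ_c [e_c/m − γ(d_c/2m)²]`; the per-level modularity trace is
recorded and non-decreasing, and on graphs small enough to enumerate all
partitions the implementation attains the brute-force maximum. Labels are
renumbered by decreasing cluster size (C0 largest). Resolution 0.5 is the
default and is the knob to move when the cluster count looks wrong; the
recovery simulations below find the planted K = 3 structure at the
default.

## Markers

One-vs-rest (and pairwise) Wilcoxon rank-sum tests on log-normalized
values, two-sided normal approximation with tie and continuity correction
(`stats::wilcox.test`), at n = m = 3 within 0.08 of the exact permutation
p-value on tie-free data. Fold change is
`ln((mean(expm1(in)) + 1)/(mean(expm1(out)) + 1))`. Genes are reported
when `max(pct_in, pct_out) ≥ 0.1` and `|logFC| ≥ 0.25`; the BH correction
is applied within each comparison **across all genes eligible by the
detection filter**, not only across the fold-change survivors — selecting
genes by their observed fold change and correcting only among them
inflates the FDR (in null label permutations it produced significant
"markers" in every run, from 3-gene BH denominators). The fold-change
filter therefore shapes the reported table but not the correction
denominator.

## Potency scores

Score(cell, category) = Σ of log-normalized expression over the category's
marker panel — additive over panel partitions by construction. Population
splits use the kernel density estimate (Silverman bandwidth) of the pooled
scores: local maxima at least 5% of the top density are candidate modes,
adjacent peaks whose separating antimode is deeper than 90% of the lower
peak are merged (a shoulder is not a mode), and the threshold is the
antimode between the two highest surviving modes; unimodal distributions
fall back to the median and are flagged (`n_modes = 1`). Constant scores
and sets of fewer than 30 values are handled explicitly. The housekeeping
panel acts as the negative control: it should stay unimodal.

`compare_populations()` computes one threshold on the pooled scores so all
groups are cut on a common scale, then per-group high fractions (strictly
greater than the threshold) and pairwise Wilcoxon p-values.
`cd_rank()`/`top_set_overlap()` rank surface-marker genes by mean
expression or detection fraction and compare top-50 sets;
`phenotype_fraction()` gates cells on ≥1 UMI for every positive and 0 UMI
for every negative marker. The shipped marker panels and CD list
(`inst/extdata/*_synthetic*`) are representative stand-ins to be replaced
with study-specific tables.

## The simulator

`simulate_umi()` draws `NB(μ, θ)` counts with
`μ = base_mean × libsize × batch × cluster × cycle`:

* gene base means log-normal(meanlog = log 1.25, sdlog = 1.5), giving
  ~25–40k UMIs per cell over 6–10k genes — the depth regime of
  high-coverage cultured-cell experiments and deliberately deep enough
  that the mean-0.1 gene filter bites only the low tail;
* per-cell library factors log-normal(0, 0.35); per-donor per-gene batch
  factors log-normal(0, 0.3); global θ = 10;
* a 13-gene mitochondrial block rescaled to an expected 8% of each cell's
  UMIs (typical for healthy cultures), with moderate spread so no single
  mito gene dominates;
* S and G2/M modules (50 genes each) bumped by ln(2) in the corresponding
  phase; default phase mix 23% G1 / 43% S / 34% G2M, the proportions of a
  strongly proliferating culture;
* K = 3 clusters with 40 disjoint DE genes each at ln(3), 300 cells per
  donor × 3 donors;
* six 20-gene marker panels, optionally coupled to a cluster via
  `panel_effects`.

Structural gene blocks (cycle modules, panels, DE genes) draw their base
means from the upper half of the base-mean distribution
(`structural_min_quantile = 0.5`): program and marker genes in real
cultured-cell data — histones, collagens, proliferation markers — are
robustly expressed, and a "marker" below the abundance filter is not a
marker in any usable sense. `spike_outliers()` plants known library-size
outliers by binomial thinning for testing the QC stage.

The simulator emulates multiplicative batch/cycle/cluster structure on
independent NB genes. It does **not** model gene–gene correlation beyond
the planted modules, doublets, ambient RNA, zero inflation beyond NB
sampling, or continuous differentiation trajectories. Passing tests
therefore establish that each stage does what it claims under its own
statistical assumptions — not that those assumptions hold in any given
real dataset, nor that printed dataset-specific figures (cell counts after
QC, a particular HVG total, a six-cluster partition, specific potency
percentages) will be reproduced, since those depend on the deposited data
and on list/threshold choices their authors did not fully specify.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale on
one CPU: 500–1,000 cells for QC/phase checks, 2,000 cells × 300 genes for
residual calibration, 900 cells × 6,000 genes for the full recovery
pipeline (≈ 20 s), 20 replicate seeds for the null-rate checks, and
exhaustive partition enumeration up to 8 nodes for the Louvain oracle.
Every stochastic step takes an explicit seed; `run_pipeline()` derives all
stage seeds from one root seed and records every parameter in its
manifest, from which a run can be reproduced exactly.

## Known limitations

* The NB regression uses a Poisson working fit for the mean coefficients
  (with ML only for θ); at extreme overdispersion with strong depth trends
  the coefficient estimates are slightly less efficient than a full NB
  IRLS, though the regularization absorbs most of the difference.
* Louvain is a greedy heuristic: optimality is only guaranteed (and
  checked) on enumerable graphs; on real graphs the seed controls the node
  visiting order and can change labels for borderline cells.
* The KDE mode/dip rules (5% height, 90% dip) are pragmatic conventions
  for "two major peaks"; distributions with genuinely shallow separation
  will be called unimodal and fall back to the median threshold.
* Potency scores summarize marker transcription; they are not evidence of
  differentiation capacity, which requires functional assays.
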