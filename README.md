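# mscpop

Dissecting subpopulation heterogeneity in cultured mesenchymal stromal
cells (MSCs) from droplet single-cell RNA-seq UMI counts.

Cultured MSC products — e.g. Wharton's-jelly MSCs expanded from umbilical
cord — pass the ISCT minimal criteria (CD105+/CD73+/CD90+, CD45−/CD34−/…)
yet behave heterogeneously in the clinic. This package re-implements, as a
tested and reusable pipeline, the single-cell workflow used to resolve that
heterogeneity: QC filtering, cell-cycle assignment, consensus
highly-variable-gene selection, confound regression, graph clustering,
marker detection, and marker-panel lineage potency scoring. A
negative-binomial simulator with known truth (clusters, batch, cycle,
marker modules) makes every stage verifiable end to end without any data
download.

## The model in brief

* **Cell QC.** Within each donor, a cell is removed when `log(total UMI)`
  or `log(detected genes)` falls below, or the mitochondrial fraction rises
  above, `median ± 3 × 1.4826 × MAD`. Genes with mean UMI < 0.1 across the
  pooled donors are removed.
* **Normalization.** `ln(1 + 10^4 · x / total)` for scoring and DE; for
  clustering, per-gene negative-binomial regression of counts on
  `log10(total)` with dispersion θ, parameters regularized by local-linear
  kernel regression over `log10(gene mean)`, giving Pearson residuals
  `(x − μ)/sqrt(μ + μ²/θ)` clipped at `±sqrt(n)`.
* **Cell cycle.** Per-cell S and G2/M module scores = mean expression of
  the program minus the mean of expression-matched control genes drawn from
  24 equal-frequency bins; phase = G1 if both ≤ 0, else the larger score.
* **Consensus HVGs.** Genes ranked by variance standardized against a
  loess mean–variance trend, top 2000 per donor per phase; phases
  intersected within donor, donors united.
* **Clustering.** Residuals on the HVG set, OLS regression of
  (s_score, g2m_score, donor) out of each gene, PCA (20 PCs), shared
  nearest-neighbor graph (k = 20, Jaccard weights, prune 1/15), Louvain
  modularity optimization (resolution 0.5), clusters named C0, C1, … by
  decreasing size.
* **Markers.** One-vs-rest and pairwise Wilcoxon rank-sum tests on
  log-normalized values with Benjamini–Hochberg correction,
  `min_pct = 0.1`, `|logFC| ≥ 0.25` (natural log).
* **Potency.** Score(cell, lineage) = Σ of log-normalized expression over
  the lineage marker panel (osteogenic, chondrogenic, adipogenic, myogenic,
  neurogenic; housekeeping as the unimodal control); a population's "high
  fraction" is the share of cells right of the antimode of the score's
  kernel density estimate.

## Worked example

```r
library(mscpop)

sim <- simulate_umi(sim_config(n_genes = 6000, seed = 101))
res <- run_pipeline(sim$matrix, pipeline_config(seed = 1),
                    mito_genes = sim$truth$mito_genes,
                    s_genes    = sim$truth$s_genes,
                    g2m_genes  = sim$truth$g2m_genes)

res$reports$cells            # qc_report: cells 900 -> 893 ( 7 removed )
length(res$hvg$hvg)          # 751 consensus HVGs
table(res$labels)            # clusters C0..C2: 311 292 290
head(res$markers[res$markers$fdr < 0.05, c("cluster", "gene", "logFC", "fdr")])
```

On this simulated three-donor cohort (300 cells/donor, three
subpopulations with 40 DE genes each at ln(3), batch sd 0.3, cycle effect
ln(2)) the pipeline removes 7 outlier cells, selects 751 consensus HVGs,
and recovers the three planted subpopulations exactly (adjusted Rand index
1.0 against truth; donor labels are mixed, ARI ≈ 0); all 120 planted
marker genes that survive the gene filter are recovered at FDR < 0.05 with
no false positives. The same workflow, stage by stage with narrative
output and result tables, is in `analysis/01_simulate.R` …
`analysis/06_potency.R` (run them in order from the repository root).

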