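# Shared simulation fixtures, built once per test run.

local_fixture_env <- new.env(parent = emptyenv())

# K = 3 recovery simulation at the documented study-like conditions:
# 300 cells/donor x 3 donors, DE ln(3) on 40 genes/cluster, batch sd 0.3,
# cycle effect ln(2); 6000 genes keeps the full pipeline run ~20 s.
recovery_fixture <- function() {
  if (is.null(local_fixture_env$recovery)) {
    cfg <- sim_config(n_genes = 6000, seed = 101)
    sim <- simulate_umi(cfg)
    res <- suppressWarnings(suppressMessages(
      run_pipeline(sim$matrix, pipeline_config(seed = 1),
                   mito_genes = sim$truth$mito_genes,
                   s_genes = sim$truth$s_genes,
                   g2m_genes = sim$truth$g2m_genes)))
    local_fixture_env$recovery <- list(sim = sim, res = res,
                                       keep = match(res$cells$barcode,
                                                    sim$matrix$barcodes))
  }
  local_fixture_env$recovery
}

# Small matrix for container/IO tests.
toy_umi <- function() {
  umi_matrix(matrix(c(2, 3, 0, 0, 1, 5), nrow = 3,
                    dimnames = list(c("b1", "b2", "b3"), c("g1", "g2"))),
             donor = "A")
}

# A log-normalized matrix with pure background structure (Poisson counts,
# varying depth) for module-score null tests.
background_lognorm <- function(n_cells, n_genes, seed = 1) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(1), 1)
  lib <- rlnorm(n_cells, 0, 0.3)
  cnt <- matrix(rpois(n_cells * n_genes, outer(lib, base)), n_cells)
  um <- umi_matrix(cnt, barcodes = sprintf("c%05d", seq_len(n_cells)),
                   genes = sprintf("g%04d", seq_len(n_genes)))
  lognormalize(um)
}
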