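test_that("per-cell QC metrics follow the definitions", {
  um <- umi_matrix(matrix(c(2, 3, 0, 4, 1, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
                          dimnames = list(c("b1", "b2", "b3"),
                                          c("g1", "g2", "g3"))))
  expect_message(qc <- compute_cell_qc(um), "zero total")
  expect_equal(qc$total_umi, c(5L, 5L, 0L))
  expect_equal(qc$n_genes, c(2L, 2L, 0L))
  expect_equal(qc$pct_mito, c(0, 0, 0))

  qc2 <- suppressMessages(compute_cell_qc(um, mito_genes = "g2"))
  expect_equal(qc2$pct_mito, c(3 / 5, 1 / 5, 0))
  expect_error(compute_cell_qc(um, "not_a_gene"), "absent")
})

test_that("MAD flags match the hand-computed and degenerate cases", {
  expect_false(any(mad_outlier_flags(rep(4, 10), 3, "both")))

  x <- c(4.0, 4.1, 3.9, 4.2, 3.8, 1.0)
  # median 3.95, MAD 0.15, lower bound 3.95 - 3*1.4826*0.15 = 3.28283
  fl <- mad_outlier_flags(x, 3, "lower")
  expect_identical(which(fl), 6L)

  expect_warning(fl0 <- mad_outlier_flags(c(0, 0, 0, 0, 10), 3, "upper"),
                 "MAD is zero")
  expect_identical(which(fl0), 5L)
})

test_that("MAD flags equal a brute-force implementation on random vectors", {
  set.seed(99)
  for (i in 1:100) {
    x <- switch(1 + i %% 3,
                rnorm(sample(5:60, 1)),
                rpois(sample(5:60, 1), 3),
                rcauchy(sample(5:60, 1)))
    side <- sample(c("lower", "upper", "both"), 1)
    nm <- runif(1, 1, 4)
    expect_identical(suppressWarnings(mad_outlier_flags(x, nm, side)),
                     brute_mad_flags(x, nm, side))
  }
})

test_that("spiked low-depth cells are removed and null removals are rare", {
  cfg <- sim_config(n_genes = 1500, n_cells_per_donor = 500, n_clusters = 1,
                    n_de_genes_per_cluster = 0, batch_effect_sd = 0,
                    libsize_sdlog = 0.2, seed = 7)
  sim <- simulate_umi(cfg)
  sp <- spike_outliers(sim$matrix, 10, 0.01, seed = 8)
  qc <- compute_cell_qc(sp$matrix, sim$truth$mito_genes)
  f <- filter_cells(sp$matrix, qc, nmads = 3)
  removed <- setdiff(sp$matrix$barcodes, f$matrix$barcodes)
  expect_gte(sum(sp$spiked %in% removed), 9)
  expect_lte(length(setdiff(removed, sp$spiked)), 0.01 * 500)

  cfg0 <- sim_config(n_genes = 1500, n_cells_per_donor = 500, n_clusters = 1,
                     n_de_genes_per_cluster = 0, batch_effect_sd = 0,
                     libsize_sdlog = 0.05, seed = 2)
  sim0 <- simulate_umi(cfg0)
  qc0 <- compute_cell_qc(sim0$matrix, sim0$truth$mito_genes)
  f0 <- filter_cells(sim0$matrix, qc0)
  expect_lte(f0$report$n_cells_removed, 0.01 * 500)
})

test_that("filtering with frozen thresholds is idempotent", {
  cfg <- sim_config(n_genes = 800, n_cells_per_donor = c(150, 150),
                    n_clusters = 1, n_de_genes_per_cluster = 0, seed = 12)
  sim <- simulate_umi(cfg)
  qc <- compute_cell_qc(sim$matrix, sim$truth$mito_genes)
  f1 <- filter_cells(sim$matrix, qc, nmads = 3)
  qc2 <- qc[match(f1$matrix$barcodes, qc$barcode), , drop = FALSE]
  f2 <- filter_cells(f1$matrix, qc2, bounds = f1$report$bounds)
  expect_equal(f2$report$n_cells_removed, 0)
})

test_that("tiny donors are skipped and gene filter applies the boundary rule", {
  um <- umi_matrix(matrix(rpois(8, 5), 2, dimnames = list(c("b1", "b2"),
                                                          paste0("g", 1:4))),
                   donor = c("A", "A"))
  qc <- compute_cell_qc(um)
  expect_warning(filter_cells(um, qc), "fewer than 3")

  # 10 cells, gene total 1 -> mean exactly 0.1 is retained
  cnt <- cbind(rep(1, 10), c(1, rep(0, 9)), c(1, 1, rep(0, 8)), rep(0, 10))
  dimnames(cnt) <- list(sprintf("b%02d", 1:10), c("keepA", "bound", "keepB", "zero"))
  um2 <- umi_matrix(cnt)
  fg <- filter_genes_by_mean(um2, min_mean = 0.1)
  expect_setequal(fg$matrix$genes$gene_id, c("keepA", "bound", "keepB"))
  expect_equal(fg$report$n_genes_removed, 1)

  # 20 cells, total 1 -> mean 0.05 removed
  cnt3 <- cbind(rep(1, 20), c(1, rep(0, 19)))
  dimnames(cnt3) <- list(sprintf("b%02d", 1:20), c("hi", "lo"))
  expect_identical(filter_genes_by_mean(umi_matrix(cnt3))$matrix$genes$gene_id,
                   "hi")
})

test_that("qc reports are internally consistent", {
  rec <- recovery_fixture()
  rep_c <- rec$res$reports$cells
  expect_equal(rep_c$n_cells_in, rep_c$n_cells_removed + rep_c$n_cells_kept)
  rep_g <- rec$res$reports$genes
  expect_equal(rep_g$n_genes_in, rep_g$n_genes_removed + rep_g$n_genes_kept)
})
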