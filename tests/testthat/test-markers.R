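test_that("rank-sum test handles symmetric, degenerate and extreme inputs", {
  r <- wilcoxon_rank_sum(c(1, 2), c(1, 2))
  expect_equal(r$U, 2)
  expect_equal(r$p, 1)

  expect_equal(wilcoxon_rank_sum(rep(3, 5), rep(3, 4))$p, 1)

  set.seed(15)
  x <- rnorm(50, 5); y <- rnorm(50, 0)
  expect_lt(wilcoxon_rank_sum(x, y)$p, 1e-10)

  # U + U' = n * m on arbitrary inputs
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    expect_equal(wilcoxon_rank_sum(a, b)$U + wilcoxon_rank_sum(b, a)$U,
                 length(a) * length(b))
  }
})

test_that("normal approximation tracks the exact permutation p at n = m = 3", {
  set.seed(16)
  d <- replicate(50, {
    x <- rnorm(3); y <- rnorm(3, 0.5)
    abs(wilcoxon_rank_sum(x, y)$p - perm_rank_sum_p(x, y))
  })
  expect_lt(max(d), 0.08)
})

test_that("BH adjustment matches hand computations", {
  expect_equal(bh_fdr(0.042), 0.042)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)) >= 0))
})

test_that("log fold change follows the pseudocount convention", {
  v <- c(log1p(3), log1p(3), log1p(1), log1p(1))
  expect_equal(log_fold_change(v, 1:2, 3:4), log(4 / 2))
  expect_equal(log_fold_change(rep(0, 4), 1:2, 3:4), 0)
  expect_equal(log_fold_change(c(1, 1, 1, 1), 1:2, 3:4), 0)
  expect_error(log_fold_change(v, 1:2, 2:3), "disjoint|intersect")
})

test_that("label permutations of one population yield no significant markers", {
  set.seed(17)
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 600, n_cells_per_donor = 200, n_clusters = 1,
                      n_de_genes_per_cluster = 0, batch_effect_sd = 0,
                      seed = 700 + s)
    ln <- lognormalize(simulate_umi(cfg)$matrix)
    labels <- sample(rep(0:1, each = 100))
    mk <- find_markers(ln, labels)
    sum(mk$fdr < 0.05)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("simulated DE genes are recovered with high precision and recall", {
  cfg <- sim_config(n_genes = 1200, n_cells_per_donor = 300, n_clusters = 2,
                    n_de_genes_per_cluster = 40, de_logfc = log(3),
                    batch_effect_sd = 0, seed = 18)
  sim <- simulate_umi(cfg)
  ln <- lognormalize(sim$matrix)
  mk <- find_markers(ln, sim$truth$cluster)
  truth_de <- unlist(sim$truth$de_genes)
  sig <- unique(mk$gene[mk$fdr < 0.05 & mk$logFC > 0])
  expect_gte(mean(truth_de %in% sig), 0.9)
  expect_gte(mean(sig %in% truth_de), 0.9)
})

test_that("filters, cluster size guards and label invariance behave", {
  set.seed(19)
  cnt <- matrix(rpois(60 * 50, 2), 60,
                dimnames = list(sprintf("c%02d", 1:60), sprintf("g%02d", 1:50)))
  ln <- lognormalize(umi_matrix(cnt))
  labels <- rep(0:1, each = 30)
  expect_equal(nrow(find_markers(ln, labels, min_logfc = Inf)), 0)

  # invariance to cluster id renaming: cluster 0 vs rest == cluster 1 vs rest
  # after flipping the labels
  mk1 <- find_markers(ln, labels, min_pct = 0, min_logfc = 0)
  mk2 <- find_markers(ln, 1 - labels, min_pct = 0, min_logfc = 0)
  a <- mk1[mk1$cluster == 0, c("gene", "logFC", "p_value")]
  b <- mk2[mk2$cluster == 1, c("gene", "logFC", "p_value")]
  expect_equal(a[order(a$gene), ], b[order(b$gene), ], ignore_attr = TRUE)

  # invariance to cell order
  perm <- sample(60)
  ln_p <- ln; ln_p$values <- ln$values[perm, ]
  mk3 <- find_markers(ln_p, labels[perm], min_pct = 0, min_logfc = 0)
  c3 <- mk3[mk3$cluster == 0, c("gene", "logFC", "p_value")]
  expect_equal(a[order(a$gene), ], c3[order(c3$gene), ], ignore_attr = TRUE)

  labels_small <- c(rep(0, 57), rep(1, 2), 2)
  expect_warning(find_markers(ln, labels_small), "fewer than 3")
  expect_error(find_markers(ln, rep(0, 60)), "2 clusters")
})
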