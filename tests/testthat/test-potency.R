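test_that("potency scores are panel sums and additive over partitions", {
  V <- rbind(c(1, 2, 0, 0.5), c(0, 0, 0, 0))
  dimnames(V) <- list(c("c1", "c2"), c("g1", "g2", "g3", "g4"))
  ln <- norm_matrix(V, "lognorm")
  sc <- potency_score(ln, list(osteo = c("g1", "g2")))
  expect_equal(unname(sc[, "osteo"]), c(3, 0))

  # adding an all-zero gene changes nothing
  sc2 <- potency_score(ln, list(osteo = c("g1", "g2", "g3")))
  expect_equal(sc2[, "osteo"], sc[, "osteo"])

  # additivity over a disjoint partition of the panel
  full <- potency_score(ln, list(p = c("g1", "g2", "g4")))
  parts <- potency_score(ln, list(a = c("g1", "g2"), b = "g4"))
  expect_equal(unname(full[, "p"]), unname(parts[, "a"] + parts[, "b"]))

  expect_error(potency_score(ln, list(bad = "nope")), "no gene")
})

test_that("bimodal threshold lands between well-separated modes", {
  set.seed(20)
  sc <- c(rnorm(1000), rnorm(1000, 10))
  bt <- bimodal_threshold(sc)
  expect_equal(bt$n_modes, 2L)
  expect_gt(bt$threshold, 3)
  expect_lt(bt$threshold, 7)

  uni <- rnorm(1000, 5)
  bu <- bimodal_threshold(uni)
  expect_equal(bu$n_modes, 1L)
  expect_equal(bu$threshold, median(uni))

  expect_equal(bimodal_threshold(rep(2.5, 50)),
               list(threshold = 2.5, n_modes = 1L))
  expect_error(bimodal_threshold(rnorm(10)))
})

test_that("high_fraction recovers mixing weights and obeys edge cases", {
  set.seed(21)
  sc <- c(rnorm(2000), rnorm(3000, 10))    # mixing weight 0.6 above
  bt <- bimodal_threshold(sc)
  expect_lt(abs(high_fraction(sc, bt$threshold) - 0.6), 0.02)

  expect_equal(high_fraction(sc, -Inf), 1)
  expect_equal(high_fraction(sc, max(sc)), 0)
})

test_that("population comparison uses a pooled threshold and Wilcoxon p", {
  set.seed(22)
  # null: two random halves of one population (large groups so the
  # fraction standard error is well inside the 0.03 band)
  base <- c(rnorm(5000), rnorm(5000, 8))
  ok <- replicate(20, {
    grp <- sample(rep(c("a", "b"), 5000))
    cmp <- compare_populations(split(base, grp))
    abs(diff(cmp$fractions)) < 0.03 && cmp$p_values$p > 0.05
  })
  expect_gte(mean(ok), 0.95)

  # constructed shift: one cluster's osteogenic panel up by ln(2)
  cfg <- sim_config(n_genes = 1500, n_cells_per_donor = 600, n_clusters = 2,
                    n_de_genes_per_cluster = 0, batch_effect_sd = 0,
                    panel_effects = list(list(category = "osteogenic",
                                              cluster = 1, logfc = log(2))),
                    seed = 23)
  sim <- simulate_umi(cfg)
  ln <- lognormalize(sim$matrix)
  sc <- potency_score(ln, sim$truth$marker_panels["osteogenic"])
  cmp <- compare_populations(split(sc[, 1], sim$truth$cluster))
  expect_gt(cmp$fractions[["0"]], cmp$fractions[["1"]])
  expect_lt(cmp$p_values$p, 0.001)

  expect_warning(compare_populations(list(a = rnorm(40), b = rnorm(40), c = 1)),
                 "excluded")
})

test_that("CD ranking orders genes by both criteria", {
  V <- rbind(c(2.0, 0.1, 0), c(1.5, 0.2, 0), c(1.0, 0, 0))
  dimnames(V) <- list(paste0("c", 1:3), c("high", "low", "zero"))
  ln <- norm_matrix(V, "lognorm")
  rk <- cd_rank(ln, c("high", "low", "zero"), criterion = "mean")
  expect_identical(rk$gene, c("high", "low", "zero"))
  expect_equal(rk$pct_cells[rk$gene == "high"], 1)
  expect_equal(rk$mean_expr[rk$gene == "high"], 1.5)
  expect_equal(rk$rank_mean[rk$gene == "zero"], 3)
  expect_equal(rk$rank_pct[rk$gene == "zero"], 3)
  rk2 <- cd_rank(ln, c("high", "low", "zero"), criterion = "pct")
  expect_identical(rk2$gene[1], "high")
})

test_that("top-set overlap partitions the two rankings", {
  a <- data.frame(gene = sprintf("g%02d", 1:60))
  expect_equal(lengths(top_set_overlap(a, a, 50)),
               c(shared = 50L, unshared_a = 0L, unshared_b = 0L))
  b <- data.frame(gene = c(sprintf("g%02d", 1:30), sprintf("x%02d", 1:30)))
  ov <- top_set_overlap(a, b, 50)
  expect_length(ov$shared, 30)
  expect_length(ov$unshared_a, 20)
  expect_length(ov$unshared_b, 20)
  disj <- data.frame(gene = sprintf("y%02d", 1:50))
  expect_length(top_set_overlap(a, disj, 50)$shared, 0)
})

test_that("phenotype fractions count strict +/- marker combinations", {
  cnt <- rbind(c(2, 0, 1), c(1, 1, 1), c(0, 0, 5), c(3, 0, 0))
  dimnames(cnt) <- list(paste0("c", 1:4), c("pos1", "neg1", "pos2"))
  um <- umi_matrix(cnt)
  # pos1+ neg1- pos2+ -> only c1
  expect_equal(phenotype_fraction(um, c("pos1", "pos2"), "neg1"), 1 / 4)
  expect_equal(phenotype_fraction(um, "pos1"), 3 / 4)
  # a negative marker expressed everywhere excludes all cells
  um2 <- umi_matrix(matrix(1, 3, 1, dimnames = list(paste0("c", 1:3), "neg")))
  expect_equal(phenotype_fraction(um2, character(0), "neg"), 0)
  expect_error(phenotype_fraction(um, "missing_gene"), "absent")
  expect_error(phenotype_fraction(um), "at least one")
})
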