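test_that("regression removes covariate signal and keeps unrelated genes", {
  set.seed(8)
  n <- 400
  s <- rnorm(n); g2m <- rnorm(n)
  # orthogonal to the covariates by construction
  y_free <- stats::resid(stats::lm(rnorm(n) ~ s + g2m))
  y_dep <- 2 * s + rnorm(n, sd = 0.1)
  Y <- cbind(free = y_free, dep = y_dep)
  covs <- data.frame(s_score = s, g2m_score = g2m)
  out <- scale_and_regress(norm_matrix(Y, "nb_residual"), covs)
  expect_gt(cor(out$values[, "free"], y_free - mean(y_free)), 0.999)
  expect_lt(abs(cor(out$values[, "dep"], s)), 1e-8)
  # residuals orthogonal to every covariate column at machine precision
  expect_lt(max(abs(crossprod(cbind(s, g2m), out$values))), 1e-8 * n)
})

test_that("scaled residuals are clipped and collinear covariates dropped", {
  set.seed(9)
  y <- c(rnorm(400), 40)             # extreme outlier ~> z-score beyond 10
  Y <- matrix(y, dimnames = list(NULL, "g"))
  covs <- data.frame(a = rnorm(401))
  out <- scale_and_regress(norm_matrix(Y, "nb_residual"), covs, clip = 10)
  expect_equal(max(out$values), 10)

  covs2 <- data.frame(a = covs$a, b = 2 * covs$a)
  expect_warning(scale_and_regress(norm_matrix(Y, "nb_residual"), covs2),
                 "collinear")
})

test_that("PCA matches closed-form eigen structure", {
  set.seed(10)
  # rank-1 data: all variance on PC1
  u <- rnorm(100)
  Y1 <- outer(u, c(1, 2, -1))
  e1 <- run_pca(Y1, n_pcs = 2)
  expect_gt(e1$variance_explained[1], 1 - 1e-10)

  # exact sample covariance [[2,1],[1,2]] -> eigenvalue shares 3/4 and 1/4
  Z <- matrix(rnorm(400), 200, 2)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  W <- Z %*% solve(chol(stats::cov(Z)))       # whiten: cov(W) = I
  Y2 <- W %*% chol(matrix(c(2, 1, 1, 2), 2))  # cov(Y2) = [[2,1],[1,2]] exactly
  e2 <- run_pca(Y2, n_pcs = 2)
  expect_equal(e2$variance_explained, c(0.75, 0.25), tolerance = 1e-10)
  expect_equal(sum(e2$variance_explained), 1)

  expect_error(run_pca(Y2, n_pcs = 5), "exceeds")
})

test_that("SNN graph matches brute-force Jaccard enumeration", {
  # 2 cells, k = 1: identical neighbor sets, one edge of weight 1
  g2 <- snn_graph(matrix(c(0, 1), 2, 1), k = 1, prune = 0)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$weight, 1)

  # 4 collinear equidistant points, k = 2, plus random configurations
  set.seed(11)
  configs <- c(list(matrix(c(1, 2, 3, 4), 4, 1)),
               lapply(1:5, function(i) matrix(rnorm(2 * sample(6:15, 1)),
                                              ncol = 2)))
  for (S in configs) {
    k <- min(3, nrow(S) - 1)
    got <- snn_graph(S, k = k, prune = 1 / 15)
    want <- brute_snn_edges(S, k, 1 / 15)
    got_o <- got$edges[order(got$edges$i, got$edges$j), ]
    expect_equal(unname(as.matrix(got_o)), unname(want), tolerance = 1e-12)
  }
})

test_that("well-separated blobs produce no cross-blob edges", {
  set.seed(12)
  S <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
             matrix(rnorm(40, 50, 0.1), ncol = 2))
  g <- snn_graph(S, k = 10, prune = 1 / 15)
  blob <- rep(1:2, each = 20)
  expect_true(all(blob[g$edges$i] == blob[g$edges$j]))
})

test_that("modularity matches hand computations and igraph", {
  e <- data.frame(i = c(1, 2, 1, 4, 5, 4), j = c(2, 3, 3, 5, 6, 6), weight = 1)
  g <- make_snn(as.matrix(e), 6)
  expect_equal(graph_modularity(g, rep(1, 6)), 0)
  expect_equal(graph_modularity(g, c(1, 1, 1, 2, 2, 2)), 0.5)

  skip_if_not_installed("igraph")
  set.seed(13)
  ig_edges <- cbind(sample(1:10), sample(1:10))
  ig_edges <- ig_edges[ig_edges[, 1] != ig_edges[, 2], , drop = FALSE]
  w <- runif(nrow(ig_edges))
  g2 <- make_snn(cbind(pmin(ig_edges[, 1], ig_edges[, 2]),
                       pmax(ig_edges[, 1], ig_edges[, 2]), w), 10)
  memb <- sample(1:3, 10, replace = TRUE)
  ig <- igraph::graph_from_edgelist(ig_edges, directed = FALSE)
  expect_equal(graph_modularity(g2, memb),
               igraph::modularity(ig, memb, weights = w), tolerance = 1e-12)
})

test_that("Louvain attains the brute-force maximum modularity on small graphs", {
  # two disconnected triangles split into components
  e <- cbind(c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6), 1)
  g <- make_snn(e, 6)
  lab <- louvain_cluster(g, resolution = 1, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(attr(lab, "modularity"), 0.5)

  set.seed(14)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < 0.5
    if (!any(keep)) next
    em <- cbind(pairs[keep, 1], pairs[keep, 2], runif(sum(keep), 0.2, 1))
    g <- make_snn(em, n)
    best <- max(vapply(all_partitions(n),
                       function(p) graph_modularity(g, p), numeric(1)))
    lab <- louvain_cluster(g, resolution = 1, seed = rep)
    expect_equal(graph_modularity(g, lab), best, tolerance = 1e-9)
    # modularity never decreases across levels
    expect_true(all(diff(attr(lab, "q_history")) >= -1e-12))
  }

  expect_identical(as.integer(louvain_cluster(g, seed = 3)),
                   as.integer(louvain_cluster(g, seed = 3)))
  expect_error(louvain_cluster(make_snn(matrix(numeric(0), 0, 3), 0)), "empty")
})

test_that("cluster labels are ordered by decreasing size", {
  rec <- recovery_fixture()
  sizes <- table(rec$res$labels)
  expect_identical(names(sizes), as.character(seq_along(sizes) - 1))
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("regressed clustering recovers truth and mixes donors", {
  rec <- recovery_fixture()
  truth <- rec$sim$truth
  lab <- rec$res$labels
  expect_gte(ari(lab, truth$cluster[rec$keep]), 0.9)
  expect_lte(abs(ari(lab, truth$donor[rec$keep])), 0.05)
  skip_if_not_installed("mclust")
  expect_equal(ari(lab, truth$cluster[rec$keep]),
               mclust::adjustedRandIndex(lab, truth$cluster[rec$keep]),
               tolerance = 1e-12)
})
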