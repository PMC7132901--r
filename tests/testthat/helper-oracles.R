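# Independent oracles used across test files.

# Brute-force MAD outlier flags: explicit sort/median/absolute-deviation
# implementation, no shared code with mad_outlier_flags().
brute_mad_flags <- function(values, nmads, side) {
  srt <- sort(values)
  n <- length(srt)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  devs <- sort(abs(values - med))
  mad <- if (n %% 2 == 1) devs[(n + 1) / 2] else (devs[n / 2] + devs[n / 2 + 1]) / 2
  lo <- values < med - nmads * 1.4826 * mad
  hi <- values > med + nmads * 1.4826 * mad
  switch(side, lower = lo, upper = hi, both = lo | hi)
}

# All set partitions of n elements (n small), as label vectors.
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, k)
  }
  out
}

# Exact two-sided permutation p-value of the rank-sum statistic.
perm_rank_sum_p <- function(x, y) {
  z <- c(x, y)
  n <- length(x)
  rk <- rank(z)
  obs <- sum(rk[seq_len(n)])
  idx <- utils::combn(length(z), n)
  stats <- apply(idx, 2, function(ii) sum(rk[ii]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Brute-force SNN: neighbor sets (self + k nearest, ties by index) and
# Jaccard weights enumerated pair by pair.
brute_snn_edges <- function(S, k, prune) {
  n <- nrow(S)
  d <- as.matrix(stats::dist(S))
  sets <- lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    c(i, setdiff(ord, i)[seq_len(k)])
  })
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- length(intersect(sets[[i]], sets[[j]]))
    w <- ov / length(union(sets[[i]], sets[[j]]))
    if (ov > 0 && w >= prune) out <- rbind(out, c(i, j, w))
  }
  out
}

# Adjusted Rand index (mclust is the cross-check where available).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ind <- si * sj / n2
  (sij - exp_ind) / ((si + sj) / 2 - exp_ind)
}

make_snn <- function(edges, n) {
  structure(list(edges = data.frame(i = edges[, 1], j = edges[, 2],
                                    weight = edges[, 3]),
                 n = n, k = NA, prune = 0), class = "snn_graph")
}
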