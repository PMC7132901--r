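#' Regress nuisance covariates out of normalized expression and scale
#'
#' Per gene, fits ordinary least squares of expression on the covariates
#' (plus intercept), z-scores the residuals and clips them. Collinear
#' covariate columns are dropped with a warning. Used to remove cell-cycle
#' scores and donor/batch indicators before PCA.
#'
#' @param norm A `norm_matrix` (typically Pearson residuals restricted to
#'   the HVG set).
#' @param covariates data.frame or matrix of per-cell covariates, rows
#'   aligned to cells; character/factor columns are expanded to indicators.
#' @param clip Symmetric bound on the scaled residuals (default 10).
#' @return A `norm_matrix` with method `"scaled"`.
#' @export
scale_and_regress <- function(norm, covariates, clip = 10) {
  Y <- as.matrix(norm$values)
  stopifnot(nrow(Y) == NROW(covariates))
  cov_df <- as.data.frame(covariates, stringsAsFactors = TRUE)
  X <- stats::model.matrix(~ ., data = cov_df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    warning("dropping collinear covariate column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
    qr_x <- qr(X)
  }
  res <- qr.resid(qr_x, Y)
  sd_g <- apply(res, 2, stats::sd)
  sd_g[sd_g == 0] <- 1
  res <- sweep(res, 2, sd_g, `/`)
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  norm_matrix(res, "scaled",
              params = list(covariates = colnames(X)[-1], source = norm$method),
              clip = clip)
}

#' Principal component analysis of a scaled matrix
#'
#' Singular value decomposition of the column-centered matrix.
#'
#' @param norm A `norm_matrix` (or plain matrix), cells x genes.
#' @param n_pcs Number of components to keep (default 20).
#' @return List of class `embedding`: `scores` (cells x n_pcs), `loadings`
#'   (genes x n_pcs), `variance_explained` (fraction of total variance per
#'   kept PC).
#' @export
run_pca <- function(norm, n_pcs = 20) {
  Y <- if (inherits(norm, "norm_matrix")) as.matrix(norm$values) else as.matrix(norm)
  if (n_pcs > min(dim(Y)))
    stop("n_pcs (", n_pcs, ") exceeds min(cells, genes) = ", min(dim(Y)))
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE, rank. = n_pcs)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x,
                 loadings = pc$rotation,
                 variance_explained = ve[seq_len(n_pcs)]),
            class = "embedding")
}

#' Shared-nearest-neighbor graph
#'
#' Each cell's neighbor set is itself plus its `k` nearest neighbors by
#' Euclidean distance in PC space (distance ties broken by cell index).
#' Edge weight between two cells is the Jaccard overlap of their neighbor
#' sets; edges with weight below `prune` are dropped, as are self-loops.
#'
#' @param embedding An `embedding` (or a cells x dims matrix).
#' @param k Number of nearest neighbors (default 20).
#' @param prune Minimum Jaccard weight kept (default 1/15).
#' @return List of class `snn_graph`: `edges` (data.frame `i`, `j`,
#'   `weight` with `i < j`), `n`, `k`, `prune`.
#' @export
snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  S <- if (inherits(embedding, "embedding")) embedding$scores else as.matrix(embedding)
  n <- nrow(S)
  stopifnot(k < n)
  d <- as.matrix(stats::dist(S))
  # neighbor sets: self + k nearest (ties by index)
  nb <- matrix(0L, n, k + 1)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    nb[i, ] <- c(i, ord[seq_len(k)])
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1), j = as.vector(nb),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)
  inter <- methods::as(methods::as(inter, "generalMatrix"), "TsparseMatrix")
  keep <- inter@i < inter@j
  ii <- inter@i[keep] + 1L; jj <- inter@j[keep] + 1L; ov <- inter@x[keep]
  w <- ov / (2 * (k + 1) - ov)
  keep2 <- w >= prune
  structure(list(edges = data.frame(i = ii[keep2], j = jj[keep2],
                                    weight = w[keep2]),
                 n = n, k = k, prune = prune),
            class = "snn_graph")
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ e_c/m - gamma * (d_c / 2m)^2 ]` where `e_c` is the total
#' intra-community edge weight, `d_c` the summed weighted degree of the
#' community and `m` the total edge weight.
#'
#' @param graph An `snn_graph` (or list with an `edges` data.frame and `n`).
#' @param labels Community label per node.
#' @param resolution Resolution parameter gamma (default 1).
#' @return Modularity value.
#' @export
graph_modularity <- function(graph, labels, resolution = 1) {
  e <- graph$edges
  stopifnot(length(labels) == graph$n)
  m <- sum(e$weight)
  if (m == 0) return(0)
  intra <- tapply(e$weight[labels[e$i] == labels[e$j]],
                  labels[e$i][labels[e$i] == labels[e$j]], sum)
  deg <- numeric(graph$n)
  ds <- rowsum(c(e$weight, e$weight), c(e$i, e$j))
  deg[as.integer(rownames(ds))] <- ds[, 1]
  d_c <- tapply(deg, labels, sum)
  e_c <- rep(0, length(d_c)); names(e_c) <- names(d_c)
  if (length(intra)) e_c[names(intra)] <- intra
  sum(e_c / m - resolution * (d_c / (2 * m))^2)
}

# One local-moving level of the Louvain algorithm on an edge matrix.
# em: matrix with columns i, j, w (i may equal j for aggregated self-loops).
louvain_one_level <- function(em, n, gamma) {
  # adjacency list excluding self-loops; self-loop weight tracked separately
  self_w <- numeric(n)
  sl <- em[, 1] == em[, 2]
  if (any(sl)) self_w[em[sl, 1]] <- self_w[em[sl, 1]] + em[sl, 3]
  e2 <- em[!sl, , drop = FALSE]
  both <- rbind(e2, e2[, c(2, 1, 3), drop = FALSE])
  adj <- split(seq_len(nrow(both)), both[, 1])
  deg <- numeric(n)
  for (v in seq_len(n)) {
    rows <- adj[[as.character(v)]]
    deg[v] <- sum(both[rows, 3]) + 2 * self_w[v]
  }
  m <- sum(em[, 3])
  comm <- seq_len(n)
  tot <- deg            # sum of degrees per community
  improved_any <- FALSE
  repeat {
    moved <- 0L
    for (v in sample.int(n)) {
      rows <- adj[[as.character(v)]]
      cv <- comm[v]
      tot[cv] <- tot[cv] - deg[v]
      # weight from v to each neighboring community
      if (length(rows)) {
        ncomm <- comm[both[rows, 2]]
        w_to <- tapply(both[rows, 3], ncomm, sum)
      } else w_to <- numeric(0)
      cand <- unique(c(cv, as.integer(names(w_to))))
      gain <- vapply(cand, function(cc) {
        kin <- if (as.character(cc) %in% names(w_to)) w_to[[as.character(cc)]] else 0
        kin / m - gamma * deg[v] * tot[cc] / (2 * m^2)
      }, numeric(1))
      best <- cand[which.max(gain)]
      comm[v] <- best
      tot[best] <- tot[best] + deg[v]
      if (best != cv) { moved <- moved + 1L; improved_any <- TRUE }
    }
    if (moved == 0L) break
  }
  list(comm = match(comm, sort(unique(comm))), improved = improved_any)
}

louvain_aggregate <- function(em, comm) {
  ci <- comm[em[, 1]]; cj <- comm[em[, 2]]
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  key <- paste(lo, hi)
  agg <- rowsum(em[, 3], key)
  parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  cbind(as.integer(parts[, 1]), as.integer(parts[, 2]), as.numeric(agg))
}

#' Louvain community detection on an SNN graph
#'
#' Greedy modularity optimization with a resolution parameter: repeated
#' local-moving passes followed by graph aggregation until modularity stops
#' improving. Final labels are renumbered by decreasing community size
#' (0 = largest, matching the C0..Ck naming convention). The modularity
#' after each level is recorded in the `"q_history"` attribute and is
#' non-decreasing by construction.
#'
#' @param graph An `snn_graph`.
#' @param resolution Resolution gamma (default 0.5); larger values give
#'   more, smaller communities.
#' @param seed Integer seed for the node visiting order.
#' @return Integer vector of 0-based cluster labels per cell.
#' @export
louvain_cluster <- function(graph, resolution = 0.5, seed = 0L) {
  e <- graph$edges
  if (nrow(e) == 0 || graph$n == 0) stop("empty graph")
  set.seed(seed)
  em <- cbind(e$i, e$j, e$weight)
  n <- graph$n
  membership <- seq_len(n)
  q_hist <- numeric(0)
  repeat {
    lev <- louvain_one_level(em, n, resolution)
    membership <- lev$comm[membership]
    q_hist <- c(q_hist, graph_modularity(graph, membership, resolution))
    if (!lev$improved) break
    em <- louvain_aggregate(em, lev$comm)
    n <- max(lev$comm)
  }
  # isolated nodes (no edges) keep their own community via membership init
  sizes <- table(membership)
  new_id <- stats::setNames(seq_along(sizes) - 1L,
                            names(sort(sizes, decreasing = TRUE)))
  labels <- as.integer(new_id[as.character(membership)])
  attr(labels, "q_history") <- q_hist
  attr(labels, "modularity") <- q_hist[length(q_hist)]
  labels
}
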