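#' Marker-panel lineage potency scores
#'
#' For each category (e.g. osteogenic, chondrogenic, adipogenic, myogenic,
#' neurogenic, plus a housekeeping control panel), the per-cell score is the
#' sum of log-normalized expression over the panel genes. Panel genes absent
#' from the matrix are dropped with a message; a category with no present
#' gene is an error.
#'
#' @param norm A `norm_matrix` with method `"lognorm"`.
#' @param panels Named list: category -> character vector of gene ids.
#' @return Matrix of scores, cells x categories.
#' @export
potency_score <- function(norm, panels) {
  stopifnot(length(panels) >= 1, !is.null(names(panels)))
  V <- norm$values
  cols <- lapply(names(panels), function(cat) {
    present <- intersect(panels[[cat]], colnames(V))
    if (length(present) == 0)
      stop("category ", cat, " has no gene present in the matrix")
    if (length(present) < length(panels[[cat]]))
      message(cat, ": ", length(panels[[cat]]) - length(present),
              " panel gene(s) absent, dropped")
    Matrix::rowSums(V[, present, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(V), names(panels))
  out
}

#' Density-based bimodal threshold
#'
#' Gaussian kernel density estimate (Silverman rule-of-thumb bandwidth) of
#' the scores; local maxima of the density are modes. With two or more
#' modes, the threshold is the antimode — the argmin of the density between
#' the two highest modes. With a single mode the median is returned as a
#' fallback and flagged via `n_modes = 1`.
#'
#' @param scores Numeric vector (at least 30 values).
#' @return List with `threshold` and `n_modes`.
#' @export
bimodal_threshold <- function(scores) {
  stopifnot(length(scores) >= 30)
  if (length(unique(scores)) == 1)
    return(list(threshold = scores[1], n_modes = 1L))
  d <- stats::density(scores, bw = "nrd0")
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (y[1] > y[2]) is_max <- c(1, is_max)
  if (y[length(y)] > y[length(y) - 1]) is_max <- c(is_max, length(y))
  # major peaks only: drop negligible tail bumps (< 5% of the top density),
  # then merge adjacent peaks without a substantial dip between them
  # (antimode deeper than 90% of the lower peak is no real separation)
  is_max <- is_max[y[is_max] >= 0.05 * max(y)]
  while (length(is_max) >= 2) {
    dips <- vapply(seq_len(length(is_max) - 1), function(k) {
      between <- is_max[k]:is_max[k + 1]
      min(y[between]) / min(y[is_max[k]], y[is_max[k + 1]])
    }, numeric(1))
    if (max(dips) <= 0.9) break
    k <- which.max(dips)
    drop_k <- if (y[is_max[k]] < y[is_max[k + 1]]) k else k + 1
    is_max <- is_max[-drop_k]
  }
  n_modes <- length(is_max)
  if (n_modes < 2)
    return(list(threshold = stats::median(scores), n_modes = 1L))
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- lo:hi
  list(threshold = d$x[between[which.min(y[between])]],
       n_modes = as.integer(n_modes))
}

#' Fraction of scores above a threshold
#'
#' @param scores Numeric vector.
#' @param threshold Finite threshold.
#' @return Fraction of scores strictly greater than `threshold`.
#' @export
high_fraction <- function(scores, threshold) {
  stopifnot(is.finite(threshold) || threshold == -Inf)
  mean(scores > threshold)
}

#' Compare potency score distributions between populations
#'
#' Computes a shared threshold from the pooled scores (so all groups are cut
#' on a common scale), the per-group high-score fractions, and pairwise
#' Wilcoxon rank-sum p-values. Groups with fewer than 3 cells are excluded.
#'
#' @param scores_by_group Named list of numeric score vectors.
#' @return List with `threshold`, `n_modes`, `fractions` (named vector) and
#'   `p_values` (data.frame `group_a`, `group_b`, `p`).
#' @export
compare_populations <- function(scores_by_group) {
  stopifnot(length(scores_by_group) >= 2, !is.null(names(scores_by_group)))
  keep <- vapply(scores_by_group, length, integer(1)) >= 3
  if (any(!keep))
    warning("group(s) with fewer than 3 cells excluded: ",
            paste(names(scores_by_group)[!keep], collapse = ", "))
  scores_by_group <- scores_by_group[keep]
  pooled <- unlist(scores_by_group, use.names = FALSE)
  thr <- bimodal_threshold(pooled)
  fractions <- vapply(scores_by_group, high_fraction,
                      numeric(1), threshold = thr$threshold)
  groups <- names(scores_by_group)
  pairs <- utils::combn(groups, 2)
  p_values <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    p = apply(pairs, 2, function(gp)
      wilcoxon_rank_sum(scores_by_group[[gp[1]]], scores_by_group[[gp[2]]])$p),
    stringsAsFactors = FALSE)
  list(threshold = thr$threshold, n_modes = thr$n_modes,
       fractions = fractions, p_values = p_values)
}

#' Rank CD (cluster of differentiation) genes
#'
#' Ranks surface-marker genes by mean normalized expression or by the
#' fraction of cells with at least one UMI; both statistics are reported.
#'
#' @param norm A `norm_matrix` with method `"lognorm"`.
#' @param cd_genes Character vector of CD gene ids.
#' @param criterion `"mean"` or `"pct"`.
#' @return data.frame sorted by the chosen criterion (descending) with
#'   columns `gene`, `mean_expr`, `pct_cells`, `rank_mean`, `rank_pct`.
#' @export
cd_rank <- function(norm, cd_genes, criterion = c("mean", "pct")) {
  criterion <- match.arg(criterion)
  V <- norm$values
  present <- intersect(cd_genes, colnames(V))
  if (length(present) == 0) stop("no CD gene present in the matrix")
  mean_expr <- Matrix::colMeans(V[, present, drop = FALSE])
  pct_cells <- Matrix::colMeans(V[, present, drop = FALSE] > 0)
  out <- data.frame(gene = present, mean_expr = mean_expr,
                    pct_cells = pct_cells,
                    rank_mean = rank(-mean_expr, ties.method = "first"),
                    rank_pct = rank(-pct_cells, ties.method = "first"),
                    stringsAsFactors = FALSE)
  out[order(if (criterion == "mean") out$rank_mean else out$rank_pct), ,
      drop = FALSE]
}

#' Overlap of two top-n ranked gene sets
#'
#' @param ranking_a,ranking_b `cd_rank()` outputs (or data.frames with a
#'   `gene` column ordered by rank).
#' @param n Top size (default 50).
#' @return List with `shared`, `unshared_a`, `unshared_b`.
#' @export
top_set_overlap <- function(ranking_a, ranking_b, n = 50) {
  stopifnot(nrow(ranking_a) >= n, nrow(ranking_b) >= n)
  a <- ranking_a$gene[seq_len(n)]
  b <- ranking_b$gene[seq_len(n)]
  list(shared = intersect(a, b),
       unshared_a = setdiff(a, b),
       unshared_b = setdiff(b, a))
}

#' Fraction of cells matching a +/- marker phenotype
#'
#' A cell matches when it has at least one UMI for every positive marker and
#' zero UMIs for every negative marker (e.g. the skeletal-stem-cell
#' phenotype PDPN+ MCAM- NT5E+ CD164+).
#'
#' @param um A [umi_matrix()].
#' @param positive,negative Character vectors of gene ids (at least one of
#'   the two must be nonempty; missing genes are an error).
#' @return Fraction of matching cells.
#' @export
phenotype_fraction <- function(um, positive = character(0), negative = character(0)) {
  if (length(positive) + length(negative) == 0)
    stop("at least one positive or negative marker is required")
  missing <- setdiff(c(positive, negative), um$genes$gene_id)
  if (length(missing))
    stop("marker gene(s) absent: ", paste(missing, collapse = ", "))
  ok <- rep(TRUE, length(um$barcodes))
  for (g in positive)
    ok <- ok & (um$counts[, match(g, um$genes$gene_id)] >= 1)
  for (g in negative)
    ok <- ok & (um$counts[, match(g, um$genes$gene_id)] == 0)
  mean(ok)
}
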