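#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test with tie correction and continuity correction.
#' When every value in both groups is identical the test is undefined and
#' `p = 1` is returned with `U = nm/2`.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return List with `U` (the Mann-Whitney statistic of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (all(c(x, y) == c(x, y)[1]))
    return(list(U = length(x) * length(y) / 2, p = 1))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE,
                       alternative = "two.sided"))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(U = unname(wt$statistic), p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in the original order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Natural-log fold change between two cell groups
#'
#' `ln((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))` on log-normalized
#' values; the pseudocount of 1 keeps all-zero groups finite.
#'
#' @param values Log-normalized per-cell values of one gene.
#' @param in_cells,out_cells Disjoint index vectors into `values`.
#' @return Log fold change (natural log).
#' @export
log_fold_change <- function(values, in_cells, out_cells) {
  stopifnot(length(in_cells) > 0, length(out_cells) > 0,
            length(intersect(in_cells, out_cells)) == 0)
  log((mean(expm1(values[in_cells])) + 1) /
        (mean(expm1(values[out_cells])) + 1))
}

marker_one_comparison <- function(V, in_idx, out_idx, cluster_id, comparison,
                                  min_pct, min_logfc) {
  pct_in <- Matrix::colMeans(V[in_idx, , drop = FALSE] > 0)
  pct_out <- Matrix::colMeans(V[out_idx, , drop = FALSE] > 0)
  mean_in <- Matrix::colMeans(expm1_values(V[in_idx, , drop = FALSE]))
  mean_out <- Matrix::colMeans(expm1_values(V[out_idx, , drop = FALSE]))
  lfc <- log((mean_in + 1) / (mean_out + 1))
  eligible <- pmax(pct_in, pct_out) >= min_pct
  test <- which(eligible & abs(lfc) >= min_logfc)
  if (length(test) == 0)
    return(empty_marker_table())
  p <- vapply(test, function(g)
    wilcoxon_rank_sum(V[in_idx, g], V[out_idx, g])$p, numeric(1))
  # BH over all genes eligible for this comparison: genes held back only by
  # the fold-change filter still count toward the correction denominator,
  # otherwise data-driven selection would inflate the FDR
  fdr <- stats::p.adjust(p, method = "BH", n = sum(eligible))
  out <- data.frame(cluster = cluster_id, comparison = comparison,
                    gene = colnames(V)[test],
                    logFC = lfc[test], pct_in = pct_in[test],
                    pct_out = pct_out[test], p_value = p,
                    fdr = fdr, stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

expm1_values <- function(v) {
  if (methods::is(v, "sparseMatrix")) { v@x <- expm1(v@x); v } else expm1(v)
}

empty_marker_table <- function() {
  data.frame(cluster = integer(0), comparison = character(0),
             gene = character(0), logFC = numeric(0), pct_in = numeric(0),
             pct_out = numeric(0), p_value = numeric(0), fdr = numeric(0),
             stringsAsFactors = FALSE)
}

#' Marker genes by Wilcoxon rank-sum test
#'
#' One-vs-rest (per cluster against all others) or pairwise differential
#' expression on log-normalized values. Genes enter the test only when
#' `max(pct_in, pct_out) >= min_pct` and `|logFC| >= min_logfc`; BH
#' correction is applied within each comparison; rows are sorted by p-value.
#' Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param norm A `norm_matrix` with method `"lognorm"`.
#' @param labels Cluster label per cell.
#' @param mode `"one_vs_rest"` or `"pairwise"`.
#' @param min_pct Minimum detection fraction in either group (default 0.1).
#' @param min_logfc Minimum absolute natural-log fold change (default 0.25).
#' @return data.frame with columns `cluster`, `comparison`, `gene`, `logFC`,
#'   `pct_in`, `pct_out`, `p_value`, `fdr`.
#' @export
find_markers <- function(norm, labels, mode = c("one_vs_rest", "pairwise"),
                         min_pct = 0.1, min_logfc = 0.25) {
  mode <- match.arg(mode)
  V <- norm$values
  stopifnot(nrow(V) == length(labels))
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("at least 2 clusters are required")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("cluster(s) with fewer than 3 cells skipped: ",
            paste(small, collapse = ", "))
    cl <- setdiff(cl, type.convert(small, as.is = TRUE))
  }
  out <- list()
  if (mode == "one_vs_rest") {
    for (k in cl) {
      in_idx <- which(labels == k); out_idx <- which(labels != k)
      out[[length(out) + 1]] <- marker_one_comparison(
        V, in_idx, out_idx, k, paste0(k, "_vs_rest"), min_pct, min_logfc)
    }
  } else {
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
      if (a >= b) next
      in_idx <- which(labels == cl[a]); out_idx <- which(labels == cl[b])
      out[[length(out) + 1]] <- marker_one_comparison(
        V, in_idx, out_idx, cl[a], paste0(cl[a], "_vs_", cl[b]),
        min_pct, min_logfc)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
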