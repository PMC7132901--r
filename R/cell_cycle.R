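#' Module score with expression-matched control bins
#'
#' For a gene set, the per-cell score is the mean normalized expression of
#' the set minus the mean over a control set. Controls are drawn per target
#' gene from its average-expression bin among `n_bins` equal-frequency bins
#' of all genes, which makes the score robust to depth and to the overall
#' expression level of the set: a set that behaves like background scores
#' around zero.
#'
#' @param norm A `norm_matrix` (log-normalized).
#' @param gene_set Character vector of gene ids; genes absent from the
#'   matrix are dropped (error if none remain).
#' @param n_bins Number of equal-frequency expression bins (default 24).
#' @param n_ctrl Control genes sampled per target gene (default 100),
#'   without replacement within each bin (capped at the bin size).
#' @param seed Integer seed for control sampling.
#' @return Numeric per-cell score vector.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100, seed = 0L) {
  v <- norm$values
  present <- intersect(gene_set, colnames(v))
  if (length(present) == 0)
    stop("no gene of the set is present in the matrix; missing: ",
         paste(gene_set, collapse = ", "))
  avg <- Matrix::colMeans(v)
  # equal-frequency bins over all genes
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bins) <- colnames(v)
  set.seed(seed)
  # per-target-gene matched controls: the control profile averages each
  # target gene's own bin sample, so bins are weighted exactly as in the
  # target set (a flat union would re-weight bins and bias the score)
  ctrl_profile <- rep(0, nrow(v))
  n_used <- 0L
  for (g in present) {
    pool <- setdiff(names(bins)[bins == bins[g]], present)
    if (length(pool) == 0) next
    picked <- sample(pool, min(n_ctrl, length(pool)))
    ctrl_profile <- ctrl_profile + Matrix::rowMeans(v[, picked, drop = FALSE])
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no control genes available")
  Matrix::rowMeans(v[, present, drop = FALSE]) - ctrl_profile / n_used
}

#' Assign a discrete cell-cycle phase from module scores
#'
#' G1 when both scores are non-positive; otherwise the phase of the larger
#' score, with exact ties (both positive) broken toward G2M.
#'
#' @param s_score,g2m_score Numeric vectors of per-cell module scores.
#' @return Character vector in `{"G1","S","G2M"}`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score),
            all(is.finite(s_score)), all(is.finite(g2m_score)))
  ifelse(s_score <= 0 & g2m_score <= 0, "G1",
         ifelse(s_score > g2m_score, "S", "G2M"))
}

#' Score S and G2/M programs and assign phases
#'
#' Convenience wrapper running [module_score()] on both cycle gene lists and
#' [assign_phase()] on the results.
#'
#' @inheritParams module_score
#' @param s_genes,g2m_genes Cycle program gene lists.
#' @return data.frame with `s_score`, `g2m_score`, `phase` (one row per cell).
#' @export
score_cell_cycle <- function(norm, s_genes, g2m_genes, n_bins = 24,
                             n_ctrl = 100, seed = 0L) {
  s <- module_score(norm, s_genes, n_bins, n_ctrl, seed)
  g2m <- module_score(norm, g2m_genes, n_bins, n_ctrl, seed + 1L)
  data.frame(barcode = rownames(norm$values), s_score = s, g2m_score = g2m,
             phase = assign_phase(s, g2m), stringsAsFactors = FALSE)
}

#' Canonical human cell-cycle gene lists
#'
#' Returns the widely used 43-gene S-phase and 54-gene G2/M human program
#' lists shipped with the package as editable text files
#' (`inst/extdata/cc_genes_s.txt`, `inst/extdata/cc_genes_g2m.txt`).
#'
#' @return List with character vectors `s` and `g2m`.
#' @export
cell_cycle_genes <- function() {
  list(
    s = readLines(system.file("extdata", "cc_genes_s.txt", package = "mscpop")),
    g2m = readLines(system.file("extdata", "cc_genes_g2m.txt", package = "mscpop"))
  )
}
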