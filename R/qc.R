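#' Per-cell QC metrics
#'
#' Computes, for every cell, the total UMI count, the number of detected
#' genes (at least one UMI) and the mitochondrial fraction
#' (mitochondrial UMIs / total UMIs; defined as 0 for empty cells, which
#' are reported with a message).
#'
#' @param um A [umi_matrix()].
#' @param mito_genes Character vector of mitochondrial gene ids (may be
#'   empty); must be a subset of the gene universe.
#' @return A data.frame (one row per cell) with columns `barcode`, `donor`,
#'   `total_umi`, `n_genes`, `pct_mito`.
#' @export
compute_cell_qc <- function(um, mito_genes = character(0)) {
  missing <- setdiff(mito_genes, um$genes$gene_id)
  if (length(missing))
    stop("mito genes absent from gene universe: ", paste(missing, collapse = ", "))
  total <- Matrix::rowSums(um$counts)
  n_genes <- Matrix::rowSums(um$counts > 0)
  mito <- if (length(mito_genes)) {
    Matrix::rowSums(um$counts[, um$genes$gene_id %in% mito_genes, drop = FALSE])
  } else rep(0, length(total))
  pct <- ifelse(total > 0, mito / total, 0)
  if (any(total == 0))
    message(sum(total == 0), " cell(s) with zero total UMI; pct_mito set to 0")
  data.frame(barcode = um$barcodes, donor = um$donor,
             total_umi = as.integer(total), n_genes = as.integer(n_genes),
             pct_mito = pct, stringsAsFactors = FALSE)
}

#' Flag outliers by the MAD rule
#'
#' A value is flagged when it lies beyond
#' `median(x) +/- nmads * 1.4826 * MAD(x)` on the tested side, with
#' `MAD = median(|x - median(x)|)` (the 1.4826 factor makes the MAD a
#' consistent estimator of the normal standard deviation). When the MAD is
#' zero but the input is not constant, every value differing from the
#' median on the tested side is flagged, with a warning.
#'
#' @param values Numeric vector.
#' @param nmads Positive cutoff in MAD units (default 3).
#' @param side One of `"lower"`, `"upper"`, `"both"`.
#' @return Logical vector, `TRUE` for flagged values.
#' @export
mad_outlier_flags <- function(values, nmads = 3, side = c("both", "lower", "upper")) {
  side <- match.arg(side)
  stopifnot(length(values) > 0, nmads > 0)
  med <- stats::median(values)
  mad <- stats::median(abs(values - med))
  if (mad == 0 && !all(values == med))
    warning("MAD is zero for a non-constant input; flagging all values off the median")
  lo <- med - nmads * 1.4826 * mad
  hi <- med + nmads * 1.4826 * mad
  flag <- rep(FALSE, length(values))
  if (side %in% c("lower", "both")) flag <- flag | values < lo
  if (side %in% c("upper", "both")) flag <- flag | values > hi
  flag
}

qc_report <- function(n_cells_in, cell_flags_by_metric, n_genes_in = NA_integer_,
                      n_genes_removed = NA_integer_, thresholds = list()) {
  removed <- if (length(cell_flags_by_metric))
    Reduce(`|`, cell_flags_by_metric) else logical(0)
  structure(list(
    n_cells_in = n_cells_in,
    n_cells_removed = sum(removed),
    n_cells_kept = n_cells_in - sum(removed),
    removed_by_metric = vapply(cell_flags_by_metric, sum, integer(1)),
    n_genes_in = n_genes_in,
    n_genes_removed = n_genes_removed,
    n_genes_kept = n_genes_in - n_genes_removed,
    thresholds = thresholds
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: cells", x$n_cells_in, "->", x$n_cells_kept,
      "(", x$n_cells_removed, "removed )\n")
  if (!is.na(x$n_genes_in))
    cat("           genes", x$n_genes_in, "->", x$n_genes_kept,
        "(", x$n_genes_removed, "removed )\n")
  invisible(x)
}

#' Remove outlier cells per donor by the MAD rule
#'
#' Within each donor independently, flags cells in the lower tail of
#' log(total UMI), the lower tail of log(detected genes), or the upper tail
#' of the mitochondrial fraction, each at `nmads` MADs from the median; the
#' union of flags is removed. Cells with zero total UMI are excluded from
#' the MAD fit and always removed. Donors with fewer than 3 cells are
#' skipped with a warning (the MAD is meaningless there).
#'
#' @param um A [umi_matrix()].
#' @param cell_table Output of [compute_cell_qc()] aligned to `um`.
#' @param nmads Cutoff in MAD units (default 3).
#' @param bounds Optional `bounds` data.frame from a previous run's report:
#'   thresholds are then reused instead of re-estimated (so filtering is
#'   idempotent; re-estimating on the filtered cells may remove more).
#' @return List with the filtered `matrix` and a `report` (a `qc_report`
#'   with per-metric removal counts and the per-donor `bounds` used).
#' @export
filter_cells <- function(um, cell_table, nmads = 3, bounds = NULL) {
  stopifnot(identical(cell_table$barcode, um$barcodes))
  n <- nrow(cell_table)
  flags <- list(low_total = rep(FALSE, n), low_genes = rep(FALSE, n),
                high_mito = rep(FALSE, n), zero_total = cell_table$total_umi == 0)
  mad_bound <- function(values, nmads, side) {
    med <- stats::median(values)
    mad <- stats::median(abs(values - med))
    med + (if (side == "lower") -1 else 1) * nmads * 1.4826 * mad
  }
  bnd <- list()
  for (d in unique(cell_table$donor)) {
    idx <- which(cell_table$donor == d & cell_table$total_umi > 0)
    if (is.null(bounds)) {
      if (length(idx) < 3) {
        warning("donor ", d, " has fewer than 3 usable cells; MAD filter skipped")
        next
      }
      b <- data.frame(
        donor = d,
        lo_log_total = mad_bound(log(cell_table$total_umi[idx]), nmads, "lower"),
        lo_log_genes = mad_bound(log(cell_table$n_genes[idx]), nmads, "lower"),
        hi_pct_mito = mad_bound(cell_table$pct_mito[idx], nmads, "upper"))
    } else {
      b <- bounds[bounds$donor == d, , drop = FALSE]
      if (nrow(b) == 0) next
    }
    bnd[[d]] <- b
    flags$low_total[idx] <- log(cell_table$total_umi[idx]) < b$lo_log_total
    flags$low_genes[idx] <- log(cell_table$n_genes[idx]) < b$lo_log_genes
    flags$high_mito[idx] <- cell_table$pct_mito[idx] > b$hi_pct_mito
  }
  report <- qc_report(n, flags, thresholds = list(nmads = nmads))
  report$bounds <- do.call(rbind, c(bnd, list(make.row.names = FALSE)))
  keep <- !Reduce(`|`, flags)
  list(matrix = subset_umi(um, cells = which(keep)), report = report,
       kept = cell_table$barcode[keep])
}

#' Remove low-abundance genes by mean UMI
#'
#' Genes whose mean UMI across all retained cells is below `min_mean` are
#' removed; a gene with mean exactly `min_mean` is retained.
#'
#' @param um A [umi_matrix()].
#' @param min_mean Minimum mean UMI per cell (default 0.1).
#' @return List with the filtered `matrix` and a `report`.
#' @export
filter_genes_by_mean <- function(um, min_mean = 0.1) {
  stopifnot(length(um$barcodes) > 0)
  means <- Matrix::colMeans(um$counts)
  keep <- means >= min_mean
  report <- qc_report(length(um$barcodes), list(),
                      n_genes_in = length(keep),
                      n_genes_removed = sum(!keep),
                      thresholds = list(min_mean = min_mean))
  list(matrix = subset_umi(um, genes = which(keep)), report = report)
}
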