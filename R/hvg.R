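#' Rank highly variable genes by standardized variance
#'
#' Per-gene variance of counts standardized by the expected standard
#' deviation at the gene's mean: a loess curve (span `loess_span`) of
#' log10(variance) on log10(mean) gives the mean-variance trend, counts are
#' z-scored against `(mean, expected sd)` with values clipped at `sqrt(n)`,
#' and the variance of the clipped z-scores is the ranking statistic.
#'
#' @param um A [umi_matrix()] (typically one donor/phase subset).
#' @param n_top Number of genes to flag as highly variable (default 2000).
#' @param loess_span Span of the mean-variance trend fit (default 0.3).
#' @return data.frame per gene: `gene_id`, `mean`, `variance`,
#'   `variance_expected`, `variance_standardized`, `rank` (1 = most
#'   variable), `top` flag. Genes with zero variance get standardized
#'   variance 0.
#' @export
hvg_vst <- function(um, n_top = 2000, loess_span = 0.3) {
  cnt <- um$counts
  n <- nrow(cnt)
  stopifnot(n >= 2)
  mu <- Matrix::colMeans(cnt)
  ex2 <- Matrix::colMeans(cnt^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  varying <- v > 0 & mu > 0
  if (!any(varying)) {
    warning("all genes constant; empty HVG ranking")
    out <- data.frame(gene_id = um$genes$gene_id, mean = mu, variance = v,
                      variance_expected = NA_real_,
                      variance_standardized = 0,
                      stringsAsFactors = FALSE)
    out$rank <- seq_len(nrow(out)); out$top <- FALSE
    return(out)
  }
  fit <- stats::loess(log10(v[varying]) ~ log10(mu[varying]), span = loess_span)
  v_exp <- rep(NA_real_, length(mu))
  v_exp[varying] <- 10^stats::fitted(fit)

  clip <- sqrt(n)
  v_std <- numeric(length(mu))
  idx <- which(varying)
  sd_exp <- sqrt(v_exp[idx])
  cnt_d <- as.matrix(cnt[, idx, drop = FALSE])
  z <- sweep(sweep(cnt_d, 2, mu[idx], `-`), 2, sd_exp, `/`)
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  v_std[idx] <- apply(z, 2, stats::var)

  if (n_top > length(mu)) {
    warning("n_top exceeds number of genes; flagging all")
    n_top <- length(mu)
  }
  rk <- rank(-v_std, ties.method = "first")
  data.frame(gene_id = um$genes$gene_id, mean = mu, variance = v,
             variance_expected = v_exp, variance_standardized = v_std,
             rank = rk, top = rk <= n_top, stringsAsFactors = FALSE)
}

#' Consensus highly variable genes across donors and phases
#'
#' Applies `within_rule` (default: intersection) over the per-phase top sets
#' of each donor, then `across_rule` (default: union) over donors; all
#' intermediate sets are recorded for Venn-style reporting.
#'
#' @param rankings Nested list: `rankings[[donor]][[phase]]` is a character
#'   vector of top gene ids.
#' @param within_rule,across_rule `"intersection"` or `"union"`.
#' @return List of class `consensus_hvg` with `per_donor_phase`,
#'   `per_donor`, `hvg` (the final set) and the rules used.
#' @export
hvg_consensus <- function(rankings, within_rule = c("intersection", "union"),
                          across_rule = c("union", "intersection")) {
  within_rule <- match.arg(within_rule)
  across_rule <- match.arg(across_rule)
  stopifnot(length(rankings) >= 1, all(lengths(rankings) >= 1))
  comb <- function(sets, rule)
    Reduce(if (rule == "intersection") intersect else union, sets)
  per_donor <- lapply(rankings, comb, rule = within_rule)
  final <- comb(per_donor, across_rule)
  if (length(final) == 0)
    stop("empty consensus HVG set; consider a larger n_top or union rules")
  structure(list(per_donor_phase = rankings, per_donor = per_donor,
                 hvg = sort(final),
                 within_rule = within_rule, across_rule = across_rule),
            class = "consensus_hvg")
}

#' @export
print.consensus_hvg <- function(x, ...) {
  cat("consensus_hvg:", length(x$hvg), "genes (",
      x$within_rule, "within donor,", x$across_rule, "across donors )\n")
  invisible(x)
}

#' Per-donor per-phase consensus HVG selection
#'
#' Splits the cells by donor and assigned phase, ranks genes with
#' [hvg_vst()] in every group with at least `min_cells` cells, and combines
#' the top sets with [hvg_consensus()].
#'
#' @param um A [umi_matrix()] (QC-filtered).
#' @param cell_table data.frame aligned to `um` with columns `donor` and
#'   `phase`.
#' @param n_top Top genes per group (default 2000).
#' @param min_cells Minimum group size to rank (default 10; smaller groups
#'   are skipped with a warning).
#' @inheritParams hvg_consensus
#' @return A `consensus_hvg`.
#' @export
consensus_hvg <- function(um, cell_table, n_top = 2000, min_cells = 10,
                          within_rule = "intersection", across_rule = "union") {
  stopifnot(nrow(cell_table) == length(um$barcodes))
  rankings <- list()
  for (d in unique(cell_table$donor)) {
    sets <- list()
    for (ph in unique(cell_table$phase[cell_table$donor == d])) {
      idx <- which(cell_table$donor == d & cell_table$phase == ph)
      if (length(idx) < min_cells) {
        warning("donor ", d, " phase ", ph, ": only ", length(idx),
                " cells; skipped")
        next
      }
      rk <- hvg_vst(subset_umi(um, cells = idx), n_top = n_top)
      sets[[ph]] <- rk$gene_id[rk$top]
    }
    if (length(sets)) rankings[[d]] <- sets
  }
  hvg_consensus(rankings, within_rule = within_rule, across_rule = across_rule)
}
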