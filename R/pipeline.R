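#' Pipeline configuration
#'
#' Validated container of every tunable parameter of the end-to-end analysis,
#' with the package defaults. Unknown parameter names are rejected; all
#' values (including untouched defaults) are serialized into the run
#' manifest so a run can be reproduced from its manifest alone.
#'
#' @param ... Name-value overrides of the defaults: `nmads` (3),
#'   `min_gene_mean` (0.1), `scale_factor` (1e4), `n_top` (2000),
#'   `hvg_across` ("union"), `n_pcs` (20), `k` (20), `prune` (1/15),
#'   `resolution` (0.5), `min_pct` (0.1), `min_logfc` (0.25),
#'   `n_bins` (24), `n_ctrl` (100), `seed` (0).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(nmads = 3, min_gene_mean = 0.1, scale_factor = 1e4,
              n_top = 2000, hvg_across = "union", n_pcs = 20, k = 20,
              prune = 1 / 15, resolution = 0.5, min_pct = 0.1,
              min_logfc = 0.25, n_bins = 24, n_ctrl = 100, seed = 0L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(nmads > 0, min_gene_mean >= 0, scale_factor > 0, n_top >= 1,
              n_pcs >= 1, k >= 1, prune >= 0, prune <= 1, resolution > 0,
              min_pct >= 0, min_pct <= 1, min_logfc >= 0)
  })
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on an annotated UMI matrix: per-donor MAD cell
#' QC, mean-UMI gene filtering, log-normalization, cell-cycle scoring and
#' phase assignment, per-donor per-phase consensus HVG selection,
#' regularized NB Pearson residuals on the HVG set, regression of cycle
#' scores and donor out of the residuals, PCA, SNN graph, Louvain
#' clustering, one-vs-rest marker detection, and (optionally) marker-panel
#' potency scoring with a pooled bimodal threshold. All randomness derives
#' from `config$seed`; a rerun with the same inputs, config and seed is
#' identical.
#'
#' @param um A [umi_matrix()] (e.g. from [merge_donors()] or
#'   [simulate_umi()]).
#' @param config A [pipeline_config()].
#' @param mito_genes Mitochondrial gene ids (default: ids prefixed "MT-").
#' @param s_genes,g2m_genes Cycle program gene lists (default: the shipped
#'   canonical lists intersected with the matrix, falling back to an error
#'   if empty).
#' @param panels Optional named list of marker panels for potency scoring.
#' @param out_dir Optional directory: stage tables plus a JSON manifest are
#'   written there.
#' @return List with `cells` (per-cell table: QC metrics, scores, phase,
#'   cluster), `hvg`, `embedding`, `graph`, `labels`, `markers`, `potency`
#'   (or NULL), `reports`, `config`.
#' @export
run_pipeline <- function(um, config = pipeline_config(),
                         mito_genes = NULL, s_genes = NULL, g2m_genes = NULL,
                         panels = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(mito_genes))
    mito_genes <- um$genes$gene_id[startsWith(um$genes$gene_id, "MT-")]
  reports <- list()

  # 1. cell QC (per donor) then gene filter on pooled cells
  cell_qc <- compute_cell_qc(um, mito_genes)
  fc <- filter_cells(um, cell_qc, nmads = config$nmads)
  reports$cells <- fc$report
  fg <- filter_genes_by_mean(fc$matrix, min_mean = config$min_gene_mean)
  reports$genes <- fg$report
  um_f <- fg$matrix
  cells <- cell_qc[match(um_f$barcodes, cell_qc$barcode), , drop = FALSE]

  # 2. log-normalization
  ln <- lognormalize(um_f, scale_factor = config$scale_factor)

  # 3. cell-cycle scoring
  if (is.null(s_genes) || is.null(g2m_genes)) {
    cc <- cell_cycle_genes()
    if (is.null(s_genes)) s_genes <- cc$s
    if (is.null(g2m_genes)) g2m_genes <- cc$g2m
  }
  cyc <- score_cell_cycle(ln, s_genes, g2m_genes, n_bins = config$n_bins,
                          n_ctrl = config$n_ctrl, seed = config$seed)
  cells$s_score <- cyc$s_score
  cells$g2m_score <- cyc$g2m_score
  cells$phase <- cyc$phase

  # 4. consensus HVGs per donor per phase
  hvg <- consensus_hvg(um_f, cells, n_top = config$n_top,
                       across_rule = config$hvg_across)

  # 5. variance stabilization on the HVG set, regression, PCA
  um_hvg <- subset_umi(um_f, genes = match(hvg$hvg, um_f$genes$gene_id))
  nbres <- nb_regularized_residuals(um_hvg, seed = config$seed)
  covars <- data.frame(s_score = cells$s_score, g2m_score = cells$g2m_score,
                       donor = factor(cells$donor))
  if (nlevels(covars$donor) < 2) covars$donor <- NULL
  scaled <- scale_and_regress(nbres, covars)
  emb <- run_pca(scaled, n_pcs = min(config$n_pcs, min(dim(scaled$values)) - 1))

  # 6. SNN graph + Louvain
  graph <- snn_graph(emb, k = config$k, prune = config$prune)
  labels <- louvain_cluster(graph, resolution = config$resolution,
                            seed = config$seed)
  cells$cluster <- labels

  # 7. markers (one vs rest)
  markers <- find_markers(ln, labels, mode = "one_vs_rest",
                          min_pct = config$min_pct,
                          min_logfc = config$min_logfc)

  # 8. potency scoring (optional)
  potency <- NULL
  if (!is.null(panels)) {
    scores <- potency_score(ln, panels)
    potency <- list(scores = scores)
    potency$by_category <- lapply(colnames(scores), function(cat) {
      thr <- bimodal_threshold(scores[, cat])
      list(category = cat, threshold = thr$threshold, n_modes = thr$n_modes,
           high_fraction = high_fraction(scores[, cat], thr$threshold))
    })
    names(potency$by_category) <- colnames(scores)
  }

  result <- list(matrix = um_f, lognorm = ln, cells = cells, hvg = hvg,
                 embedding = emb, graph = graph, labels = labels,
                 markers = markers, potency = potency, reports = reports,
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$cells, file.path(out_dir, "cells.tsv"))
  write_tsv(data.frame(gene_id = result$hvg$hvg), file.path(out_dir, "hvg.tsv"))
  write_tsv(result$markers, file.path(out_dir, "markers.tsv"))
  if (!is.null(result$potency)) {
    pt <- do.call(rbind, lapply(result$potency$by_category, function(x)
      data.frame(category = x$category, threshold = x$threshold,
                 n_modes = x$n_modes, high_fraction = x$high_fraction)))
    write_tsv(pt, file.path(out_dir, "potency.tsv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("mscpop")),
    config = unclass(result$config),
    stages = c("cell_qc", "gene_filter", "lognormalize", "cell_cycle",
               "consensus_hvg", "nb_residuals_regress_pca", "snn_louvain",
               "markers"),
    n_cells_in = result$reports$cells$n_cells_in,
    n_cells_kept = result$reports$cells$n_cells_kept,
    n_genes_kept = result$reports$genes$n_genes_kept,
    n_hvg = length(result$hvg$hvg),
    n_clusters = length(unique(result$labels)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Default lineage marker panels
#'
#' Reads the editable marker-panel file shipped under `inst/extdata/`
#' (category and gene symbol per row, tab-separated). These panels are a
#' synthetic, representative stand-in for lineage marker tables used in MSC
#' potency scoring; substitute your own file for real analyses.
#'
#' @param path Optional path to a panels TSV (columns `category`, `gene`).
#' @return Named list: category -> character vector of gene symbols.
#' @export
marker_panels <- function(path = system.file("extdata", "marker_panels_synthetic.tsv",
                                             package = "mscpop")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df$gene, df$category)
}

#' Default CD gene list
#'
#' Reads the editable surface-marker (cluster of differentiation) gene list
#' shipped under `inst/extdata/` — a representative HGNC-style subset, to be
#' replaced with a full list for real analyses.
#'
#' @param path Optional path to a one-gene-per-line text file.
#' @return Character vector of gene symbols.
#' @export
cd_genes <- function(path = system.file("extdata", "cd_genes_synthetic.txt",
                                        package = "mscpop")) {
  readLines(path)
}
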