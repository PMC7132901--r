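#' Simulation configuration for synthetic MSC UMI data
#'
#' Builds the parameter list consumed by [simulate_umi()]. The generator
#' emulates the structure of a droplet scRNA-seq experiment on cultured
#' mesenchymal stromal cells from several donors: negative-binomial UMI
#' counts whose expected value is the product of a gene base mean, a
#' per-cell library-size factor, a per-donor multiplicative batch factor, a
#' cluster factor on designated differentially expressed genes, and a
#' cell-cycle factor on S / G2M module genes. A designated mitochondrial
#' gene block with its own mean scale makes the mitochondrial fraction
#' non-trivial, and six lineage marker panels (osteogenic, chondrogenic,
#' adipogenic, myogenic, neurogenic, housekeeping) occupy reserved gene
#' blocks so potency scoring has known truth.
#'
#' @param n_genes Total number of genes.
#' @param n_cells_per_donor Integer vector, cells per donor.
#' @param n_clusters Number of subpopulations K.
#' @param cluster_proportions Mixing proportions (length K, sums to 1).
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   per-gene base mean (UMI per cell at unit library factor).
#' @param theta Negative-binomial dispersion (variance = mu + mu^2/theta);
#'   scalar or per-gene. `Inf` gives Poisson counts.
#' @param libsize_meanlog,libsize_sdlog Log-normal parameters of the
#'   per-cell library-size factor.
#' @param batch_effect_sd SD of the per-donor per-gene multiplicative
#'   log-normal batch factor (on the natural-log scale).
#' @param cycle_fraction Named fractions of cells in G1 / S / G2M.
#' @param cycle_effect Natural-log fold bump applied to S (resp. G2M) module
#'   genes in S (resp. G2M) cells.
#' @param n_cycle_genes Genes per cycle module.
#' @param n_de_genes_per_cluster,de_logfc Differential-expression structure:
#'   each cluster up-regulates its own disjoint gene set by `exp(de_logfc)`.
#' @param n_marker_genes Genes per lineage marker panel.
#' @param panel_effects Optional list of `list(category=, cluster=, logfc=)`
#'   entries coupling a marker panel to a cluster.
#' @param n_mito_genes,mito_fraction Size of the mitochondrial gene block
#'   and the expected fraction of each cell's UMIs coming from it (default
#'   0.08, a typical fraction for healthy cultured cells); mito gene means
#'   are drawn with moderate spread (sdlog 0.5) and rescaled to meet it.
#' @param structural_min_quantile Base means of the structural gene blocks
#'   (cycle modules, marker panels, per-cluster DE genes) are drawn from the
#'   base-mean distribution truncated below this quantile (default 0.5):
#'   cluster markers and program genes in cultured-cell scRNA-seq are
#'   robustly expressed genes, not tail-of-distribution ones.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       n_cells_per_donor = c(300, 300, 300),
                       n_clusters = 3,
                       cluster_proportions = NULL,
                       base_mean_meanlog = log(1.25),
                       base_mean_sdlog = 1.5,
                       theta = 10,
                       libsize_meanlog = 0,
                       libsize_sdlog = 0.35,
                       batch_effect_sd = 0.3,
                       cycle_fraction = c(G1 = 0.2298, S = 0.4251, G2M = 0.3451),
                       cycle_effect = log(2),
                       n_cycle_genes = 50,
                       n_de_genes_per_cluster = 40,
                       de_logfc = log(3),
                       n_marker_genes = 20,
                       panel_effects = NULL,
                       n_mito_genes = 13,
                       mito_fraction = 0.08,
                       structural_min_quantile = 0.5,
                       seed = 1L) {
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (length(n_cells_per_donor) < 1 || any(n_cells_per_donor < 1))
    stop("at least one donor with at least one cell is required")
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must have length K and sum to 1")
  if (any(theta <= 0)) stop("theta must be > 0")
  cycle_fraction <- cycle_fraction / sum(cycle_fraction)
  if (!all(c("G1", "S", "G2M") %in% names(cycle_fraction)))
    stop("cycle_fraction must be named G1, S, G2M")
  reserved <- n_mito_genes + 2 * n_cycle_genes + 6 * n_marker_genes +
    n_clusters * n_de_genes_per_cluster
  if (reserved > n_genes)
    stop("n_genes too small for the reserved gene blocks (need >= ", reserved, ")")
  structure(as.list(environment()), class = "sim_config")
}

panel_categories <- c("osteogenic", "chondrogenic", "adipogenic",
                      "myogenic", "neurogenic", "housekeeping")

# Deterministic gene block layout: mito, S module, G2M module, marker panels,
# then per-cluster DE genes; remaining genes are background.
sim_gene_layout <- function(cfg) {
  at <- 0L
  take <- function(n) { idx <- at + seq_len(n); at <<- at + n; idx }
  mito <- take(cfg$n_mito_genes)
  s_mod <- take(cfg$n_cycle_genes)
  g2m_mod <- take(cfg$n_cycle_genes)
  panels <- lapply(panel_categories, function(p) take(cfg$n_marker_genes))
  names(panels) <- panel_categories
  de <- lapply(seq_len(cfg$n_clusters), function(k) take(cfg$n_de_genes_per_cluster))
  list(mito = mito, s = s_mod, g2m = g2m_mod, panels = panels, de = de)
}

sim_gene_names <- function(cfg, layout) {
  nm <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  nm[layout$mito] <- sprintf("MT-G%02d", seq_along(layout$mito))
  nm[layout$s] <- sprintf("SMOD%03d", seq_along(layout$s))
  nm[layout$g2m] <- sprintf("G2MMOD%03d", seq_along(layout$g2m))
  for (p in names(layout$panels))
    nm[layout$panels[[p]]] <- sprintf("%s%03d", toupper(substr(p, 1, 5)),
                                      seq_along(layout$panels[[p]]))
  for (k in seq_along(layout$de))
    nm[layout$de[[k]]] <- sprintf("DE.C%d.%03d", k - 1L, seq_along(layout$de[[k]]))
  nm
}

#' Simulate a UMI matrix with known truth
#'
#' Draws counts from `NB(mu, theta)` with
#' `mu = base_mean * libsize * batch * cluster * cycle` factors as described
#' in [sim_config()]. The returned truth records per-cell cluster, donor and
#' phase labels and the per-gene sets (DE genes per cluster, cycle modules,
#' marker panels, mitochondrial genes) that downstream tests recover.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (a [umi_matrix()]) and `truth`.
#' @export
simulate_umi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  layout <- sim_gene_layout(cfg)
  g_names <- sim_gene_names(cfg, layout)
  n_donors <- length(cfg$n_cells_per_donor)
  donors <- sprintf("D%d", seq_len(n_donors))
  donor <- rep(donors, cfg$n_cells_per_donor)
  n_cells <- length(donor)
  n_genes <- cfg$n_genes

  base_mean <- stats::rlnorm(n_genes, cfg$base_mean_meanlog, cfg$base_mean_sdlog)
  structural <- c(layout$s, layout$g2m, unlist(layout$panels), unlist(layout$de))
  if (length(structural) && cfg$structural_min_quantile > 0)
    base_mean[structural] <- stats::qlnorm(
      stats::runif(length(structural), cfg$structural_min_quantile, 1),
      cfg$base_mean_meanlog, cfg$base_mean_sdlog)
  if (cfg$n_mito_genes > 0) {
    mito_raw <- stats::rlnorm(cfg$n_mito_genes, cfg$base_mean_meanlog, 0.5)
    target <- cfg$mito_fraction / (1 - cfg$mito_fraction) *
      sum(base_mean[-layout$mito])
    base_mean[layout$mito] <- mito_raw * target / sum(mito_raw)
  }
  libsize <- stats::rlnorm(n_cells, cfg$libsize_meanlog, cfg$libsize_sdlog)
  batch <- matrix(stats::rlnorm(n_donors * n_genes, 0, cfg$batch_effect_sd),
                  nrow = n_donors)
  cluster <- sample.int(cfg$n_clusters, n_cells, replace = TRUE,
                        prob = cfg$cluster_proportions)
  phase <- sample(c("G1", "S", "G2M"), n_cells, replace = TRUE,
                  prob = cfg$cycle_fraction[c("G1", "S", "G2M")])

  log_fc <- matrix(0, nrow = cfg$n_clusters, ncol = n_genes)
  for (k in seq_len(cfg$n_clusters))
    log_fc[k, layout$de[[k]]] <- cfg$de_logfc
  for (pe in cfg$panel_effects) {
    idx <- layout$panels[[pe$category]]
    log_fc[pe$cluster, idx] <- log_fc[pe$cluster, idx] + pe$logfc
  }
  cycle_fc <- matrix(0, nrow = 3, ncol = n_genes,
                     dimnames = list(c("G1", "S", "G2M"), NULL))
  cycle_fc["S", layout$s] <- cfg$cycle_effect
  cycle_fc["G2M", layout$g2m] <- cfg$cycle_effect

  di <- match(donor, donors)
  log_mu <- matrix(rep(log(base_mean), each = n_cells), nrow = n_cells)
  log_mu <- log_mu + log(libsize) + log(batch)[cbind(rep(di, n_genes),
                                                     rep(seq_len(n_genes), each = n_cells))]
  log_mu <- log_mu + log_fc[cluster, , drop = FALSE] +
    cycle_fc[phase, , drop = FALSE]
  mu <- exp(log_mu)
  counts <- if (is.infinite(cfg$theta[1]) && length(cfg$theta) == 1) {
    stats::rpois(length(mu), mu)
  } else {
    size <- if (length(cfg$theta) == 1) cfg$theta else rep(cfg$theta, each = n_cells)
    stats::rnbinom(length(mu), mu = mu, size = size)
  }
  counts <- matrix(counts, nrow = n_cells)

  bc <- sprintf("CELL%05d-%s", seq_len(n_cells), donor)
  um <- umi_matrix(counts, barcodes = bc,
                   genes = data.frame(gene_id = g_names, symbol = g_names,
                                      stringsAsFactors = FALSE),
                   donor = donor)
  truth <- list(
    cluster = cluster - 1L,            # 0-based labels, C0..C(K-1)
    donor = donor,
    phase = phase,
    de_genes = lapply(layout$de, function(ix) g_names[ix]),
    s_genes = g_names[layout$s],
    g2m_genes = g_names[layout$g2m],
    marker_panels = lapply(layout$panels, function(ix) g_names[ix]),
    mito_genes = g_names[layout$mito],
    base_mean = stats::setNames(base_mean, g_names),
    libsize = stats::setNames(libsize, bc)
  )
  list(matrix = um, truth = truth)
}

#' Spike artificial depth outliers into a UMI matrix
#'
#' Randomly picks `n` cells and rescales their counts: for
#' `depth_factor < 1` each count is binomially thinned (so the expected
#' total is `depth_factor` times the original), for `depth_factor > 1`
#' Poisson counts are added to reach the expected scale. Used to plant
#' known library-size outliers for testing the MAD filter.
#'
#' @param um A [umi_matrix()].
#' @param n Number of cells to spike.
#' @param depth_factor Positive scale applied to expected totals.
#' @param seed Integer seed.
#' @return List with the modified `matrix` and the `spiked` barcodes.
#' @export
spike_outliers <- function(um, n, depth_factor, seed = 1L) {
  stopifnot(n < length(um$barcodes), depth_factor > 0)
  if (n == 0) return(list(matrix = um, spiked = character(0)))
  set.seed(seed)
  idx <- sample.int(length(um$barcodes), n)
  cnt <- as.matrix(um$counts[idx, , drop = FALSE])
  new_cnt <- if (depth_factor < 1) {
    matrix(stats::rbinom(length(cnt), size = as.integer(cnt), prob = depth_factor),
           nrow = n)
  } else if (depth_factor > 1) {
    cnt + matrix(stats::rpois(length(cnt), cnt * (depth_factor - 1)), nrow = n)
  } else cnt
  counts <- um$counts
  counts[idx, ] <- new_cnt
  out <- um
  out$counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  list(matrix = validate_umi_matrix(out), spiked = um$barcodes[idx])
}
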