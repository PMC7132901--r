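#!/usr/bin/env Rscript
# Subpopulation clustering: regularized NB Pearson residuals on the
# consensus HVGs, linear regression of cycle scores and donor out of the
# residuals, PCA, SNN graph (k = 20, Jaccard weights, prune 1/15) and
# Louvain modularity clustering (resolution 0.5). Also quantifies how much
# variance PC1 carries before confound regression versus after.

suppressPackageStartupMessages(library(mscpop))

um <- read_mtx_triplet("results/qc/filtered")
cells <- read.delim("results/hvg/cells.tsv")
stopifnot(identical(cells$barcode, um$barcodes))
hvg <- readLines("results/hvg/hvg.txt")

um_hvg <- subset_umi(um, genes = match(hvg, um$genes$gene_id))
nbres <- suppressMessages(nb_regularized_residuals(um_hvg, seed = 1))

emb_pre <- run_pca(nbres, n_pcs = 10)
message(sprintf("PC1 before regression: %.2f%% of variance (cycle + batch)",
                100 * emb_pre$variance_explained[1]))

covars <- data.frame(s_score = cells$s_score, g2m_score = cells$g2m_score,
                     donor = factor(cells$donor))
scaled <- scale_and_regress(nbres, covars)
emb <- run_pca(scaled, n_pcs = 20)
message(sprintf("PC1 after regression: %.2f%%",
                100 * emb$variance_explained[1]))

graph <- snn_graph(emb, k = 20, prune = 1 / 15)
labels <- louvain_cluster(graph, resolution = 0.5, seed = 1)
message(length(unique(labels)), " clusters (sizes ",
        paste(table(labels), collapse = ", "), "); modularity ",
        sprintf("%.3f", attr(labels, "modularity")))

truth <- read.delim("results/sim/truth_cells.tsv")
tr <- truth[match(um$barcodes, truth$barcode), ]
tab <- table(labels, tr$cluster)
message("cluster vs truth contingency:")
print(tab)

dir.create("results/cluster", showWarnings = FALSE)
cells$cluster <- labels
write.table(cells, "results/cluster/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(pc = seq_along(emb$variance_explained),
                       variance_pct_post = 100 * emb$variance_explained,
                       variance_pct_pre = c(100 * emb_pre$variance_explained,
                                            rep(NA, 10))),
            "results/cluster/pca_variance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/cluster; done")
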