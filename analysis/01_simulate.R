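#!/usr/bin/env Rscript
# Build the synthetic three-donor MSC cohort used throughout the workflow:
# 300 cells per donor, 6000 genes, three subpopulations with 40 DE genes
# each (ln 3 fold change), donor batch effects (sd 0.3) and S/G2M cycle
# programs (ln 2). Writes one 10x-style triplet directory per donor plus
# the truth tables that later steps score against.

suppressPackageStartupMessages(library(mscpop))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 6000, seed = 101)
sim <- simulate_umi(cfg)
um <- sim$matrix

message(sprintf("simulated %d cells x %d genes; median %s UMIs/cell",
                nrow(um$counts), ncol(um$counts),
                format(median(Matrix::rowSums(um$counts)), big.mark = ",")))

for (d in unique(um$donor)) {
  sub <- subset_umi(um, cells = which(um$donor == d))
  # per-donor files carry bare barcodes; merge_donors re-suffixes them with
  # the donor label, which reconstructs the truth-table barcode
  sub$barcodes <- sub(paste0("-", d, "$"), "", sub$barcodes)
  rownames(sub$counts) <- sub$barcodes
  write_mtx_triplet(sub, file.path(out, d))
  message("wrote ", file.path(out, d), " (", nrow(sub$counts), " cells)")
}

truth_cells <- data.frame(barcode = um$barcodes, donor = sim$truth$donor,
                          cluster = sim$truth$cluster, phase = sim$truth$phase)
write.table(truth_cells, file.path(out, "truth_cells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth_genes <- rbind(
  data.frame(set = "s_module", gene = sim$truth$s_genes),
  data.frame(set = "g2m_module", gene = sim$truth$g2m_genes),
  data.frame(set = "mito", gene = sim$truth$mito_genes),
  do.call(rbind, lapply(seq_along(sim$truth$de_genes), function(k)
    data.frame(set = paste0("de_cluster", k - 1), gene = sim$truth$de_genes[[k]]))),
  do.call(rbind, lapply(names(sim$truth$marker_panels), function(p)
    data.frame(set = paste0("panel_", p), gene = sim$truth$marker_panels[[p]]))))
write.table(truth_genes, file.path(out, "truth_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote truth tables; done")
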