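#!/usr/bin/env Rscript
# Quality control: per-donor MAD outlier removal on log library size, log
# detected genes and mitochondrial fraction (cutoff 3 MADs), then a pooled
# mean-UMI >= 0.1 gene filter. Writes the filtered matrix and a QC report.

suppressPackageStartupMessages(library(mscpop))

donor_dirs <- list.dirs("results/sim", recursive = FALSE)
donor_dirs <- donor_dirs[grepl("/D\\d+$", donor_dirs)]
stopifnot(length(donor_dirs) > 0)

mats <- lapply(donor_dirs, read_mtx_triplet)
um <- merge_donors(mats, basename(donor_dirs))
message("merged ", nrow(um$counts), " cells from ", length(mats), " donors")

mito <- um$genes$gene_id[startsWith(um$genes$gene_id, "MT-")]
cell_qc <- compute_cell_qc(um, mito)
fc <- filter_cells(um, cell_qc, nmads = 3)
message(fc$report$n_cells_removed, " outlier cells removed, ",
        fc$report$n_cells_kept, " kept")

fg <- filter_genes_by_mean(fc$matrix, min_mean = 0.1)
message(fg$report$n_genes_removed, " low-abundance genes removed, ",
        fg$report$n_genes_kept, " kept")

dir.create("results/qc", showWarnings = FALSE)
write_mtx_triplet(fg$matrix, "results/qc/filtered")
write.table(cell_qc, "results/qc/cell_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
report <- data.frame(
  metric = c("cells_in", "cells_removed", "cells_kept",
             names(fc$report$removed_by_metric),
             "genes_in", "genes_removed", "genes_kept"),
  value = c(fc$report$n_cells_in, fc$report$n_cells_removed,
            fc$report$n_cells_kept, fc$report$removed_by_metric,
            fg$report$n_genes_in, fg$report$n_genes_removed,
            fg$report$n_genes_kept))
write.table(report, "results/qc/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
# donor labels for downstream steps (barcodes got donor-suffixed on merge)
write.table(data.frame(barcode = fg$matrix$barcodes, donor = fg$matrix$donor),
            "results/qc/donors.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/qc; done")
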