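#!/usr/bin/env Rscript
# Cell-cycle scoring and consensus highly variable genes. Each cell gets S
# and G2/M module scores against expression-matched control bins and a
# discrete phase; genes are then ranked per donor per phase and the
# consensus set is the union over donors of the per-donor phase
# intersections.

suppressPackageStartupMessages(library(mscpop))

um <- read_mtx_triplet("results/qc/filtered")
donors <- read.delim("results/qc/donors.tsv")
um$donor <- donors$donor[match(um$barcodes, donors$barcode)]
ln <- lognormalize(um)

# simulated cycle programs are the SMOD/G2MMOD gene blocks
s_genes <- grep("^SMOD", um$genes$gene_id, value = TRUE)
g2m_genes <- grep("^G2MMOD", um$genes$gene_id, value = TRUE)
cyc <- score_cell_cycle(ln, s_genes, g2m_genes, seed = 1)
message("phase fractions: ",
        paste(sprintf("%s %.1f%%", names(table(cyc$phase)),
                      100 * table(cyc$phase) / nrow(cyc)), collapse = ", "))

truth <- read.delim("results/sim/truth_cells.tsv")
acc <- mean(cyc$phase == truth$phase[match(um$barcodes, truth$barcode)])
message(sprintf("phase assignment accuracy vs truth: %.3f", acc))

cells <- data.frame(barcode = um$barcodes, donor = um$donor,
                    s_score = cyc$s_score, g2m_score = cyc$g2m_score,
                    phase = cyc$phase)
hvg <- suppressWarnings(consensus_hvg(um, cells, n_top = 2000))
message(length(hvg$hvg), " consensus HVGs (",
        paste(sprintf("%s: %d", names(hvg$per_donor),
                      lengths(hvg$per_donor)), collapse = ", "),
        " per donor after phase intersection)")

dir.create("results/hvg", showWarnings = FALSE)
write.table(cells, "results/hvg/cells.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(hvg$hvg, "results/hvg/hvg.txt")
sets <- do.call(rbind, lapply(names(hvg$per_donor_phase), function(d)
  do.call(rbind, lapply(names(hvg$per_donor_phase[[d]]), function(ph)
    data.frame(donor = d, phase = ph,
               gene = hvg$per_donor_phase[[d]][[ph]])))))
write.table(sets, "results/hvg/per_donor_phase_sets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/hvg; done")
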