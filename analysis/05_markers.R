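#!/usr/bin/env Rscript
# Marker genes per cluster: one-vs-rest Wilcoxon rank-sum tests on
# log-normalized expression with BH correction, min_pct 0.1 and natural-log
# fold-change filter 0.25, plus the pairwise table between the two largest
# clusters. Scored against the simulation's known DE genes.

suppressPackageStartupMessages(library(mscpop))

um <- read_mtx_triplet("results/qc/filtered")
cl <- read.delim("results/cluster/clusters.tsv")
stopifnot(identical(cl$barcode, um$barcodes))
ln <- lognormalize(um)

mk <- find_markers(ln, cl$cluster, mode = "one_vs_rest")
message(nrow(mk), " marker rows; ", sum(mk$fdr < 0.05), " at FDR < 0.05")

truth_genes <- read.delim("results/sim/truth_genes.tsv")
truth_de <- truth_genes$gene[grepl("^de_cluster", truth_genes$set)]
present <- intersect(truth_de, um$genes$gene_id)
sig <- unique(mk$gene[mk$fdr < 0.05 & mk$logFC > 0])
message(sprintf("truth DE recall %.3f, precision %.3f",
                mean(present %in% sig), mean(sig %in% truth_de)))

top2 <- as.integer(names(sort(table(cl$cluster), decreasing = TRUE))[1:2])
mk_pair <- find_markers(ln, cl$cluster, mode = "pairwise")
mk_pair <- mk_pair[mk_pair$comparison == paste0(top2[1], "_vs_", top2[2]) |
                     mk_pair$comparison == paste0(top2[2], "_vs_", top2[1]), ]

dir.create("results/markers", showWarnings = FALSE)
write.table(mk, "results/markers/markers_one_vs_rest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mk_pair, "results/markers/markers_top2_pairwise.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/markers; done")
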