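#!/usr/bin/env Rscript
# Stage 5: over-representation analysis of the network-connected proteins
# against the gene-set collection (upper-tail hypergeometric test, BH FDR
# <= 0.05), followed by affinity-propagation redundancy reduction over
# Jaccard similarities of the significant sets.

suppressPackageStartupMessages(library(salivaMarkers))
nodes <- read.delim("results/network_nodes.tsv")
collection <- read_gmt("results/data/gene_sets.gmt")

res <- fisher_ora(nodes$accession, collection, fdr_cutoff = 0.05)
res <- affinity_propagation_reduce(res, collection)
write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("ORA: %d sets tested, %d significant (FDR <= 0.05), %d exemplars after redundancy reduction\n",
            nrow(res), sum(res$significant), sum(res$is_exemplar)))
truth <- read_ground_truth("results/data/ground_truth.json")
top <- res[1, ]
cat(sprintf("top set: %s (k=%d/m=%d, ER=%.1f, FDR=%.2e)%s\n",
            top$set_id, top$k, top$m, top$enrichment_ratio, top$fdr,
            if (top$set_id == truth$planted_set_id)
              " -- the planted marker set" else ""))
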