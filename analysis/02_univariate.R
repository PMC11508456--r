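#!/usr/bin/env Rscript
# Stage 2: univariate differential abundance. Log2 case/control mean fold
# change, Wilcoxon rank-sum p, BH FDR, and the joint gate (fold change
# >= 1.3 in either direction AND FDR < 0.05). Writes the volcano table.

suppressPackageStartupMessages(library(salivaMarkers))
x <- read_abundance("results/data/abundance.tsv",
                    "results/data/annotation.tsv")
tab <- univariate_table(x, fc_threshold = 1.3, alpha = 0.05)
write.table(tab, "results/volcano_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

n_sel <- sum(tab$selected)
cat(sprintf("univariate: %d of %d proteoforms selected (%.1f%% of input)\n",
            n_sel, nrow(tab), 100 * n_sel / nrow(tab)))
cat(sprintf("  %d up-regulated, %d down-regulated\n",
            attr(tab, "n_up"), attr(tab, "n_down")))

truth <- read_ground_truth("results/data/ground_truth.json")
hit <- mean(truth$marker_ids %in% tab$accession[tab$selected])
cat(sprintf("  planted-marker recall at this stage: %.0f%%\n", 100 * hit))
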