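#!/usr/bin/env Rscript
# Stage 1: simulate a salivary-proteome case/control cohort at full scale
# (2815 proteoforms, 10 cases vs 20 controls) together with a matching
# interactome (PSI-MI TAB) and gene-set collection (GMT), and write all
# inputs plus the ground truth under results/data/.

suppressPackageStartupMessages(library(salivaMarkers))
seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
sim <- simulate_abundance(cfg)
write_abundance(sim$matrix, "results/data/abundance.tsv",
                "results/data/annotation.tsv")
simulate_interactome(sim$truth, rownames(sim$matrix$values),
                     "results/data/interactome.mitab", seed = seed)
simulate_gene_sets(sim$truth, rownames(sim$matrix$values),
                   "results/data/gene_sets.gmt", n_sets = 50, seed = seed)
write_ground_truth(sim$truth, "results/data/ground_truth.json")

cat(sprintf("cohort: %d proteoforms x %d samples (%d case / %d control)\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            sum(sim$matrix$groups == "case"),
            sum(sim$matrix$groups == "control")))
cat(sprintf("planted markers: %d (|log2FC| %.1f), isoform rows: %d\n",
            length(sim$truth$marker_ids), cfg$effect_log2fc,
            sum(grepl("-", rownames(sim$matrix$values), fixed = TRUE))))
cat(sprintf("planted interactome path: %d edges among marker bases\n",
            nrow(sim$truth$planted_edges)))
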