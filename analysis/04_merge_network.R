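#!/usr/bin/env Rscript
# Stage 4: merge the univariate and multivariate selections (Venn counts),
# collapse proteoform isoforms to unique base accessions, and prune the
# interactome to interactions among the candidates (taxon 9606, protein
# interactors, no first interactors / self-loops / duplicate edges /
# isolated nodes). Writes the merged table and the network files.

suppressPackageStartupMessages(library(salivaMarkers))
uni <- read.delim("results/volcano_table.tsv")
multi <- readLines("results/multivariate_selected.txt")

merged <- merge_selections(uni$accession[uni$selected], multi, uni)
jsonlite::write_json(
  c(merged$stats, list(n_isoform_entries = merged$n_isoform_entries,
                       n_unique_bases = length(merged$bases))),
  "results/venn_counts.json", auto_unbox = TRUE, digits = NA)
write.table(merged$table, "results/merged_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("merge: %d univariate + %d multivariate, %d common -> %d combined\n",
            merged$stats$n_a, merged$stats$n_b, merged$stats$n_common,
            merged$stats$n_union))
cat(sprintf("  %d isoform entries collapsed -> %d unique base accessions\n",
            merged$n_isoform_entries, length(merged$bases)))

records <- filter_records(read_mitab("results/data/interactome.mitab"),
                          taxid = 9606, protein_only = TRUE)
net <- prune_to_input(records, merged$bases)
if (net$n_nodes > 0) net <- annotate_directions(net, merged$table)
write_network(net, "results/network_edges.tsv", "results/network_nodes.tsv",
              "results/network.graphml")
cat(sprintf("network: %d connected proteins, %d edges (%d up, %d down)\n",
            net$n_nodes, net$n_edges,
            if (is.null(net$n_up)) 0L else net$n_up,
            if (is.null(net$n_down)) 0L else net$n_down))
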