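# salivaMarkers

Biomarker selection for case/control salivary proteomics. Starting from a
label-free abundance matrix (proteoforms × samples) the package funnels
thousands of proteoforms down to a short list of physically connected,
pathway-annotated candidates — the kind of list one would take forward to
targeted validation in oral squamous cell carcinoma (OSCC) saliva studies.

The funnel has five stages, each exposed as plain functions:

1. **Univariate differential abundance** — per-proteoform log2 fold change
   of the case/control group means, two-sided Wilcoxon rank-sum p-value
   (exact for tie-free rows at these sample sizes), Benjamini–Hochberg
   FDR, and a joint gate: |FC| ≥ 1.3 (a 30 % difference either way, i.e.
   |log2FC| ≥ log2 1.3) **and** FDR < 0.05.
2. **Sparse PLS-DA with recursive feature elimination (RFE)** — the
   loading vector u of each latent component is the dominant eigenvector
   of the outer product of the protein–group cross-covariance; sample
   scores obey

   S_j = Σ_i u_i1 · r_ij

   where r_ij is the autoscaled abundance of protein i in sample j. RFE
   refits and removes the protein with the smallest |u_i1| until
   ceil(5 %) of the input list remains (2815 → 141), retaining correlated
   discriminative proteins a univariate test would miss.
3. **Merge** — union of both selections with Venn counts and collapsing of
   UniProt isoform entries (`P14618-2` → `P14618`) to unique base IDs.
4. **PPI-network pruning** — a PSI-MI TAB interactome is filtered to
   human protein–protein records, restricted to edges among the candidate
   list (removing first interactors), stripped of self-loops and duplicate
   edges, and reduced to connected proteins, each labelled up/down by its
   univariate log2FC.
5. **Over-representation analysis** — upper-tail hypergeometric test of
   the connected proteins against GMT gene sets, BH FDR ≤ 0.05, and
   affinity-propagation clustering over Jaccard similarities to flag one
   exemplar per group of redundant pathways.

A synthetic-cohort generator (`simulate_abundance()`,
`simulate_interactome()`, `simulate_gene_sets()`) reproduces the
statistical structure this analysis assumes — log-normal abundances,
correlated protein blocks, planted markers of configurable effect, isoform
entries, zero-encoded missingness, planted interactome edges and an
enriched gene set — so the entire pipeline runs and is tested offline.

## Worked example

```r
library(salivaMarkers)

cfg <- synthetic_config(n_proteins = 600, n_markers = 30, seed = 42)
sim <- simulate_abundance(cfg)
sim$matrix
#> abundance_matrix: 600 proteoforms x 30 samples (10 case, 20 control)

uni <- univariate_table(sim$matrix)
sum(uni$selected)                          # proteoforms passing FC + FDR gate
#> 18   (12 up-regulated, 6 down-regulated)

trace <- rfe(sim$matrix, n_components = 2, target_fraction = 0.05)
trace
#> rfe_trace: 600 -> 30 proteins (570 eliminated)
#> final variance explained: 36.4%, 6.5%

merged <- merge_selections(uni$accession[uni$selected], trace$retained, uni)
merged$stats
#> 18 univariate + 30 multivariate, 18 common -> 30 combined (30 unique bases)

mt <- tempfile()
simulate_interactome(sim$truth, rownames(sim$matrix$values), mt, seed = 42)
net <- prune_to_input(filter_records(read_mitab(mt)), merged$bases)
net <- annotate_directions(net, merged$table)
net
#> ppi_network: 8 nodes, 5 edges
#>   7 up-regulated, 1 down-regulated

gmt <- tempfile()
simulate_gene_sets(sim$truth, rownames(sim$matrix$values), gmt,
                   n_sets = 40, seed = 42)
coll <- read_gmt(gmt)
res <- affinity_propagation_reduce(fisher_ora(net$nodes$accession, coll), coll)
head(res[, c("set_id", "k", "m", "enrichment_ratio", "fdr", "is_exemplar")], 3)
#>            set_id k  m enrichment_ratio          fdr is_exemplar
#> 1 PATHWAY_PLANTED 5 24        12.239583 0.0004586333        TRUE
#> 2  RANDOM_SET_015 2 43         2.732558 1.0000000000       FALSE
#> 3  RANDOM_SET_040 2 44         2.670455 1.0000000000       FALSE
```

Reading the output: 18 proteoforms clear the univariate gate and RFE keeps
the 30 proteoforms (5 % of 600) that drive group discrimination, with the
final two-component model explaining 36 % + 7 % of the matrix variance; 18
of the 30 overlap the univariate list. Of the 30 unique base accessions, 8
are physically connected in the interactome (5 edges), and the
over-representation analysis ranks the generator's planted marker set
first by a wide margin (5 of its 24 members among the 8 connected
proteins, enrichment ratio 12.2, FDR 5 × 10⁻⁴) — the pipeline recovers the
planted biology.

The full-scale workflow (2815 proteoforms, 10 vs 20 samples) lives in the
numbered scripts under `analysis/` (`01_simulate.R` … `05_enrichment.R`),
which write their tables under `results/`.

A bundled real-data table, `oscc_connected_proteins()`, carries the 48
network-connected salivary proteins of a published OSCC comparison with
their univariate log2FC and FDR (30 up- and 18 down-regulated) for use as
a realistic input to the network and enrichment stages.

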