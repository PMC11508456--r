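#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with the pipeline's
#' default settings: fold-change gate 1.3 (30\% difference) on the ratio
#' scale, FDR gate 0.05, two sPLS-DA components, RFE down to 5\% of the
#' input list with single-protein elimination, human-taxon protein-only
#' interaction filtering, and ORA significance at FDR <= 0.05 with
#' affinity-propagation redundancy reduction.
#'
#' @param fc_threshold,alpha,pseudocount,fc_scale Univariate stage; see
#'   [univariate_table()].
#' @param n_components,target_fraction,chunk,keep_per_component
#'   Multivariate stage; see [rfe()].
#' @param taxid,protein_only Network stage; see [filter_records()].
#' @param fdr_cutoff,ap_damping,ap_preference ORA stage; see [fisher_ora()]
#'   and [affinity_propagation_reduce()].
#' @param seed Integer seed recorded in the manifest (the pipeline stages
#'   themselves are deterministic; the seed governs upstream simulation).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_threshold = 1.3, alpha = 0.05,
                            pseudocount = NULL,
                            fc_scale = c("ratio", "log2"),
                            n_components = 2, target_fraction = 0.05,
                            chunk = 1, keep_per_component = NULL,
                            taxid = 9606, protein_only = TRUE,
                            fdr_cutoff = 0.05, ap_damping = 0.5,
                            ap_preference = NULL, seed = 1) {
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 pseudocount = pseudocount,
                 fc_scale = match.arg(fc_scale),
                 n_components = n_components,
                 target_fraction = target_fraction, chunk = chunk,
                 keep_per_component = keep_per_component, taxid = taxid,
                 protein_only = protein_only, fdr_cutoff = fdr_cutoff,
                 ap_damping = ap_damping, ap_preference = ap_preference,
                 seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full biomarker-selection pipeline
#'
#' Executes univariate differential abundance, sPLS-DA recursive feature
#' elimination, list merging with isoform collapsing, PPI-network pruning,
#' and over-representation analysis, writing each stage's tables under
#' `out_dir` together with a JSON manifest of counts, parameters and file
#' checksums.
#'
#' @param x An [abundance_matrix].
#' @param mitab_path PSI-MI TAB interaction file (`NULL` skips the network
#'   and ORA stages).
#' @param gmt_path GMT gene-set file (`NULL` skips the ORA stage).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list. Files written: `volcano_table.tsv`
#'   (accession, log2fc, pvalue, fdr, selected), `rfe_trace.tsv`,
#'   `scores.tsv` (per-sample component scores of the final model),
#'   `venn_counts.json`, `merged_table.tsv`, `network_edges.tsv`,
#'   `network_nodes.tsv`, `network.graphml`, `enrichment.tsv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(x, mitab_path = NULL, gmt_path = NULL,
                         out_dir, config = pipeline_config()) {
  stopifnot(inherits(x, "abundance_matrix"),
            inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  manifest <- list(parameters = config[!vapply(config, is.null, logical(1))],
                   seed = config$seed,
                   n_proteins = nrow(x$values), n_samples = ncol(x$values),
                   stages = list())

  uni <- stage("univariate", {
    tab <- univariate_table(x, fc_threshold = config$fc_threshold,
                            alpha = config$alpha,
                            pseudocount = config$pseudocount,
                            fc_scale = config$fc_scale)
    utils::write.table(tab, path("volcano_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab
  })
  uni_sel <- uni$accession[uni$selected]
  manifest$stages$univariate <- list(
    n_selected = length(uni_sel),
    n_up = attr(uni, "n_up"), n_down = attr(uni, "n_down"))

  trace <- stage("splsda_rfe", {
    tr <- rfe(x, n_components = config$n_components,
              target_fraction = config$target_fraction,
              chunk = config$chunk,
              keep_per_component = config$keep_per_component)
    utils::write.table(tr$eliminated, path("rfe_trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    scores <- data.frame(sample_id = rownames(tr$final_model$scores),
                         group = unname(x$groups[rownames(tr$final_model$scores)]),
                         tr$final_model$scores, check.names = FALSE)
    names(scores)[-(1:2)] <- paste0("component_",
                                    seq_len(ncol(tr$final_model$scores)))
    utils::write.table(scores, path("scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tr
  })
  manifest$stages$multivariate <- list(
    n_retained = length(trace$retained),
    variance_explained = trace$variance_explained_final)

  merged <- stage("merge", {
    mg <- merge_selections(uni_sel, trace$retained, uni)
    jsonlite::write_json(
      c(mg$stats, list(n_isoform_entries = mg$n_isoform_entries,
                       n_unique_bases = length(mg$bases))),
      path("venn_counts.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(mg$table, path("merged_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mg
  })
  manifest$stages$merge <- c(
    merged$stats, list(n_isoform_entries = merged$n_isoform_entries,
                       n_unique_bases = length(merged$bases)))

  net <- NULL
  if (!is.null(mitab_path)) {
    net <- stage("network", {
      records <- filter_records(read_mitab(mitab_path),
                                taxid = config$taxid,
                                protein_only = config$protein_only)
      nw <- prune_to_input(records, merged$bases)
      base_stats <- merged$table
      names(base_stats)[names(base_stats) == "accession"] <- "accession"
      nw <- if (nw$n_nodes > 0) annotate_directions(nw, base_stats) else nw
      write_network(nw, path("network_edges.tsv"), path("network_nodes.tsv"),
                    path("network.graphml"))
      nw
    })
    manifest$stages$network <- list(
      n_nodes = net$n_nodes, n_edges = net$n_edges,
      n_up = if (is.null(net$n_up)) 0L else net$n_up,
      n_down = if (is.null(net$n_down)) 0L else net$n_down)
  }

  if (!is.null(gmt_path) && !is.null(net) && net$n_nodes > 0) {
    ora <- stage("ora", {
      collection <- read_gmt(gmt_path)
      res <- fisher_ora(net$nodes$accession, collection,
                        fdr_cutoff = config$fdr_cutoff)
      res <- affinity_propagation_reduce(res, collection,
                                         damping = config$ap_damping,
                                         preference = config$ap_preference)
      utils::write.table(res, path("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res
    })
    manifest$stages$ora <- list(
      n_sets = nrow(ora), n_significant = sum(ora$significant),
      n_exemplars = sum(ora$is_exemplar))
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(files)), basename(files)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
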