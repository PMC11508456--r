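#' Bundled example: network-connected salivary proteins from an OSCC cohort
#'
#' A 48-row table of PPI-network-connected salivary proteins from a
#' published oral squamous cell carcinoma case/control saliva comparison
#' (10 cases vs 20 controls), annotated with the univariate log2 fold
#' change (case over control) and Benjamini-Hochberg FDR. Rows with
#' FDR > 0.05 entered the candidate list through the multivariate (sPLS-DA)
#' selection rather than the univariate gate. Useful as a realistic input
#' for the network and enrichment stages.
#'
#' @return Data.frame with columns `accession`, `name`, `log2fc`, `fdr`.
#' @export
oscc_connected_proteins <- function() {
  utils::read.delim(
    system.file("extdata", "oscc_connected_proteins.tsv",
                package = "salivaMarkers"),
    stringsAsFactors = FALSE)
}
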