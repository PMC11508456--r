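#' Read PSI-MI TAB interaction records
#'
#' Parses a tab-separated MITAB file (15-column core dialect; interactor
#' type is taken from columns 21/22 when the file carries them, otherwise
#' recorded as "unknown"). UniProt accessions are extracted from the
#' unique-identifier columns and isoform dash suffixes are stripped to the
#' base accession; lines whose primary identifier is not `uniprotkb:` are
#' kept with `uniprot_a`/`uniprot_b` set to FALSE.
#'
#' @param path MITAB file path.
#' @return Data.frame of interaction records: `id_a`, `id_b` (base
#'   accessions or raw identifiers), `uniprot_a`, `uniprot_b` (logical),
#'   `taxid_a`, `taxid_b` (integer, NA when undeclared), `type_a`, `type_b`,
#'   `source_line`.
#' @export
read_mitab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      uniprot_a = logical(0), uniprot_b = logical(0),
                      taxid_a = integer(0), taxid_b = integer(0),
                      type_a = character(0), type_b = character(0),
                      source_line = integer(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15))
    stop(sprintf("MITAB format error: %d column(s) on line %d (need >= 15)",
                 nf[which(nf < 15)[1]], which(nf < 15)[1]), call. = FALSE)
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else "-"
  }, character(1))
  parse_id <- function(v) {
    is_up <- grepl("^uniprotkb:", v)
    acc <- ifelse(is_up, sub("^uniprotkb:", "", v), v)
    list(id = proteoform_base(acc), uniprot = is_up)
  }
  parse_taxid <- function(v) {
    m <- regmatches(v, regexpr("taxid:-?[0-9]+", v))
    out <- rep(NA_integer_, length(v))
    hit <- grepl("taxid:-?[0-9]+", v)
    out[hit] <- as.integer(sub("taxid:", "", m))
    out
  }
  parse_type <- function(v) {
    out <- rep("unknown", length(v))
    m <- regexpr("\\(([^)]*)\\)", v)
    hit <- m > 0
    txt <- regmatches(v, m)
    out[hit] <- substring(txt, 2, nchar(txt) - 1)
    out
  }
  a <- parse_id(get(1)); b <- parse_id(get(2))
  has_types <- all(nf >= 22)
  data.frame(id_a = a$id, id_b = b$id,
             uniprot_a = a$uniprot, uniprot_b = b$uniprot,
             taxid_a = parse_taxid(get(10)), taxid_b = parse_taxid(get(11)),
             type_a = if (has_types) parse_type(get(21))
                      else rep("unknown", length(lines)),
             type_b = if (has_types) parse_type(get(22))
                      else rep("unknown", length(lines)),
             source_line = seq_along(lines), stringsAsFactors = FALSE)
}

#' Filter interaction records by taxonomy and interactor type
#'
#' Keeps records where both interactors carry the target taxon (removing
#' homology-inferred cross-species rows) and, when `protein_only`, both
#' interactor types denote a protein ("unknown" is treated as protein, since
#' the 15-column MITAB core does not carry the type).
#'
#' @param records Data.frame from [read_mitab()].
#' @param taxid Target NCBI taxon (default 9606, Homo sapiens).
#' @param protein_only Drop records with a declared non-protein interactor.
#' @return The filtered records, input order preserved.
#' @export
filter_records <- function(records, taxid = 9606, protein_only = TRUE) {
  keep <- !is.na(records$taxid_a) & !is.na(records$taxid_b) &
    records$taxid_a == taxid & records$taxid_b == taxid
  if (protein_only) {
    is_protein <- function(v) v %in% c("protein", "peptide", "unknown")
    keep <- keep & is_protein(records$type_a) & is_protein(records$type_b)
  }
  records[keep, , drop = FALSE]
}

#' Prune interactions down to a network over the input proteins
#'
#' Applies the candidate-list restriction: only edges with BOTH endpoints in
#' `input_set` survive (this removes all first interactors), self-loops are
#' dropped, duplicate edges are collapsed to one undirected edge, and
#' unconnected (degree-0) proteins are excluded.
#'
#' @param records Data.frame with columns `id_a`, `id_b` (typically the
#'   output of [filter_records()]).
#' @param input_set Character vector of base accessions (the candidate
#'   biomarker list).
#' @return An object of class `ppi_network`: `nodes` (data.frame
#'   `accession`), `edges` (data.frame `a`, `b` with a < b), `n_nodes`,
#'   `n_edges`.
#' @export
prune_to_input <- function(records, input_set) {
  if (length(input_set) == 0)
    stop("`input_set` must be non-empty", call. = FALSE)
  keep <- records$id_a %in% input_set & records$id_b %in% input_set &
    records$id_a != records$id_b
  edges <- records[keep, c("id_a", "id_b"), drop = FALSE]
  if (nrow(edges) > 0) {
    g <- igraph::simplify(
      igraph::graph_from_data_frame(edges, directed = FALSE),
      remove.multiple = TRUE, remove.loops = TRUE)
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(a = pmin(el[, 1], el[, 2]),
                        b = pmax(el[, 1], el[, 2]), stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- data.frame(accession = sort(igraph::V(g)$name),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(a = character(0), b = character(0),
                        stringsAsFactors = FALSE)
    nodes <- data.frame(accession = character(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges,
                 n_nodes = nrow(nodes), n_edges = nrow(edges)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  if (!is.null(x$nodes$direction))
    cat(sprintf("  %d up-regulated, %d down-regulated\n",
                sum(x$nodes$direction == "up"),
                sum(x$nodes$direction == "down")))
  invisible(x)
}

#' Annotate network nodes with differential-abundance direction
#'
#' Each node inherits the log2 fold change and FDR of its accession in the
#' univariate table and is labelled "up" (log2FC > 0) or "down".
#'
#' @param network A `ppi_network`.
#' @param univariate_results Data.frame with columns `accession`, `log2fc`,
#'   `fdr` covering every node (base accessions).
#' @return The network with `log2fc`, `fdr`, `direction` node columns and
#'   counts `n_up`, `n_down`.
#' @export
annotate_directions <- function(network, univariate_results) {
  stopifnot(inherits(network, "ppi_network"))
  idx <- match(network$nodes$accession, univariate_results$accession)
  if (anyNA(idx))
    stop("nodes missing from the univariate table: ",
         paste(network$nodes$accession[is.na(idx)], collapse = ", "),
         call. = FALSE)
  network$nodes$log2fc <- univariate_results$log2fc[idx]
  network$nodes$fdr <- univariate_results$fdr[idx]
  network$nodes$direction <- ifelse(network$nodes$log2fc > 0, "up", "down")
  network$n_up <- sum(network$nodes$direction == "up")
  network$n_down <- sum(network$nodes$direction == "down")
  network
}

#' Write a pruned network as edge-list TSV, node-table TSV and GraphML
#'
#' @param network A `ppi_network` (annotated or not).
#' @param edges_path,nodes_path,graphml_path Output paths; any may be `NULL`
#'   to skip that file.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(network, edges_path = NULL, nodes_path = NULL,
                          graphml_path = NULL) {
  stopifnot(inherits(network, "ppi_network"))
  written <- character(0)
  if (!is.null(edges_path)) {
    utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("acc_a", "acc_b"))
    written <- c(written, edges_path)
  }
  if (!is.null(nodes_path)) {
    utils::write.table(network$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, nodes_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = network$nodes[, "accession", drop = FALSE])
    for (col in intersect(c("log2fc", "fdr", "direction"),
                          names(network$nodes)))
      g <- igraph::set_vertex_attr(g, col, value = network$nodes[[col]])
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
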