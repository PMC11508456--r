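#' Construct a proteoform abundance matrix with group labels
#'
#' The universal input of the pipeline: a nonnegative proteins-by-samples
#' abundance table (arbitrary units, zeros encode non-detection) together
#' with a two-group sample annotation (case/control).
#'
#' @param values Numeric matrix, proteoforms in rows (rownames = UniProt-style
#'   accessions, possibly with dash isoform suffixes), samples in columns
#'   (colnames = sample IDs). All values must be nonnegative.
#' @param groups Character vector of "case"/"control" labels, either named by
#'   sample ID or in column order of `values`.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values` (the matrix) and `groups` (named character vector).
#' @export
abundance_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (accessions) and colnames (sample IDs)",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate accessions in `values`", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in `values`", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundances must be finite and nonnegative", call. = FALSE)
  groups <- as.character(groups)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("`groups` must match the number of samples", call. = FALSE)
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (length(unique(groups)) < 2L)
    stop("both groups must be non-empty", call. = FALSE)
  structure(list(values = values, groups = groups),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteoforms x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix to a set of proteoforms
#'
#' @param x An `abundance_matrix`.
#' @param accessions Character vector of row accessions to keep.
#' @return An `abundance_matrix` restricted to those rows, in the given order.
#' @export
subset_proteins <- function(x, accessions) {
  stopifnot(inherits(x, "abundance_matrix"))
  bad <- setdiff(accessions, rownames(x$values))
  if (length(bad))
    stop("unknown accessions: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  abundance_matrix(x$values[accessions, , drop = FALSE], x$groups)
}

#' Write an abundance matrix and its sample annotation as TSV
#'
#' The abundance table has a leading `accession` column and one column per
#' sample; the annotation table has columns `sample_id` and `group`.
#'
#' @param x An `abundance_matrix`.
#' @param abundance_path,annotation_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_abundance <- function(x, abundance_path, annotation_path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(accession = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, abundance_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample_id = names(x$groups), group = unname(x$groups),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(abundance_path, annotation_path))
}

#' Read an abundance matrix from TSV files
#'
#' @param abundance_path TSV with first column `accession`, remaining columns
#'   samples.
#' @param annotation_path TSV with columns `sample_id` and `group`
#'   (case/control).
#' @return An `abundance_matrix`.
#' @export
read_abundance <- function(abundance_path, annotation_path) {
  df <- utils::read.delim(abundance_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"accession" %in% names(df))
    stop("abundance table must have an 'accession' column", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "accession"), drop = FALSE])
  rownames(m) <- df$accession
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  groups <- stats::setNames(ann$group, ann$sample_id)
  abundance_matrix(m, groups)
}
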