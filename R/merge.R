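#' Parse proteoform identifiers into base accession and isoform index
#'
#' UniProt isoform entries carry a dash suffix ("P14618-2"); the base
#' accession is the substring before the first dash.
#'
#' @param ids Character vector of proteoform IDs.
#' @return Data.frame with columns `raw`, `base`, `isoform_index` (NA for
#'   canonical entries).
#' @export
parse_proteoform <- function(ids) {
  base <- sub("-.*$", "", ids)
  bad <- ids[base == ""]
  if (length(bad))
    stop("malformed accession (empty base): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  has_suffix <- grepl("-", ids, fixed = TRUE)
  idx <- rep(NA_integer_, length(ids))
  idx[has_suffix] <- as.integer(sub("^[^-]*-", "", ids[has_suffix]))
  data.frame(raw = ids, base = base, isoform_index = idx,
             stringsAsFactors = FALSE)
}

# base accession only (vectorized helper used across modules)
proteoform_base <- function(ids) sub("-.*$", "", ids)

#' Union of two proteoform selections with overlap statistics
#'
#' @param set_a,set_b Character vectors of proteoform IDs (e.g. the
#'   univariate and multivariate selections).
#' @return A list: `union` (character vector), and counts `n_a`, `n_b`,
#'   `n_common`, `n_union` satisfying inclusion-exclusion.
#' @export
union_with_stats <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- union(set_a, set_b)
  list(union = u, n_a = length(set_a), n_b = length(set_b),
       n_common = length(intersect(set_a, set_b)), n_union = length(u))
}

#' Collapse proteoform isoforms to unique base accessions
#'
#' @param proteoforms Character vector of proteoform IDs.
#' @return A list: `bases` (unique base accessions, first-appearance order)
#'   and `n_isoform_entries` (members carrying a dash isoform suffix).
#' @export
collapse_isoforms <- function(proteoforms) {
  parsed <- parse_proteoform(proteoforms)
  list(bases = unique(parsed$base),
       n_isoform_entries = sum(!is.na(parsed$isoform_index)))
}

#' Merge the univariate and multivariate selections
#'
#' Combines the two proteoform lists, reports the overlap (Venn counts),
#' collapses isoforms to unique base accessions, and annotates each base
#' with the univariate statistics of its most significant proteoform
#' (smallest FDR, ties broken by smallest |raw ID|).
#'
#' @param univariate_selected Character vector of univariate-selected
#'   proteoform IDs.
#' @param multivariate_selected Character vector of RFE-retained proteoform
#'   IDs.
#' @param univariate_results Data.frame with columns `accession`, `log2fc`,
#'   `pvalue`, `fdr` (from [univariate_table()]) used to annotate bases.
#' @return A list: `stats` (from [union_with_stats()]), `n_isoform_entries`,
#'   `bases` (unique base accessions), and `table` (one row per base with
#'   inherited `log2fc`, `pvalue`, `fdr`, sorted by fdr).
#' @export
merge_selections <- function(univariate_selected, multivariate_selected,
                             univariate_results) {
  st <- union_with_stats(univariate_selected, multivariate_selected)
  cl <- collapse_isoforms(st$union)
  res <- univariate_results[univariate_results$accession %in% st$union,
                            c("accession", "log2fc", "pvalue", "fdr")]
  res$base <- proteoform_base(res$accession)
  res <- res[order(res$fdr, res$accession), ]
  tab <- res[!duplicated(res$base),
             c("base", "accession", "log2fc", "pvalue", "fdr")]
  names(tab)[1:2] <- c("accession", "proteoform")
  tab <- tab[match(intersect(cl$bases, tab$accession), tab$accession), ]
  tab <- tab[order(tab$fdr), ]
  rownames(tab) <- NULL
  list(stats = st[c("n_a", "n_b", "n_common", "n_union")],
       union = st$union, n_isoform_entries = cl$n_isoform_entries,
       bases = cl$bases, table = tab)
}
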