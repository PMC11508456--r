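#' Read a GMT gene-set collection
#'
#' Each GMT line is: set ID, description, then tab-separated member
#' accessions.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("GMT format error on line %d: need id, description and at least one member",
                 bad[1]), call. = FALSE)
  ids <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate gene-set IDs in GMT", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  structure(list(sets = sets,
                 descriptions = stats::setNames(
                   vapply(fields, `[`, character(1), 2), ids)),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the input list overlaps the set more
#' than expected by chance: with a universe of N accessions of which m lie
#' in the set and an input list of n, the p-value is the upper hypergeometric
#' tail P(X >= k) for the observed overlap k. P-values are BH-adjusted
#' across all tested sets. Members outside the universe are ignored
#' (intersected at test time). Over-representation only; depletion is not
#' tested.
#'
#' @param input_list Character vector of (base) accessions.
#' @param collection A `gene_set_collection` from [read_gmt()], or a named
#'   list of member vectors.
#' @param universe Statistical background; default is the union of all set
#'   members and the input list.
#' @param fdr_cutoff Significance cutoff on the BH FDR (default 0.05,
#'   significant when fdr <= cutoff).
#' @return Data.frame sorted by (fdr, pvalue, set_id): `set_id`, `k`
#'   (overlap), `m` (set size in universe), `n` (input size in universe),
#'   `N` (universe size), `enrichment_ratio` ((k/n)/(m/N)), `pvalue`, `fdr`,
#'   `significant`.
#' @export
fisher_ora <- function(input_list, collection, universe = NULL,
                       fdr_cutoff = 0.05) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  if (length(sets) == 0) stop("empty gene-set collection", call. = FALSE)
  input_list <- unique(input_list)
  if (is.null(universe))
    universe <- unique(c(unlist(sets, use.names = FALSE), input_list))
  universe <- unique(universe)
  n_in <- length(intersect(input_list, universe))
  if (n_in == 0)
    stop("input list does not intersect the universe", call. = FALSE)
  N <- length(universe)
  inp <- intersect(input_list, universe)
  rows <- lapply(names(sets), function(id) {
    mem <- intersect(sets[[id]], universe)
    m <- length(mem)
    k <- length(intersect(inp, mem))
    p <- if (m == 0) 1 else
      stats::phyper(k - 1, m, N - m, n_in, lower.tail = FALSE)
    er <- if (m == 0) NA_real_ else (k / n_in) / (m / N)
    data.frame(set_id = id, k = k, m = m, n = n_in, N = N,
               enrichment_ratio = er, pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$pvalue)
  res$significant <- res$fdr <= fdr_cutoff
  res <- res[order(res$fdr, res$pvalue, res$set_id), ]
  rownames(res) <- NULL
  res
}

#' Jaccard similarity matrix between gene sets
#'
#' Pairwise |intersection| / |union| of member vectors; the similarity the
#' redundancy-reduction clustering operates on. Callers restrict members to
#' the statistical universe beforehand when one is in force.
#'
#' @param sets Named list of member character vectors.
#' @return Square numeric matrix with unit diagonal.
#' @export
jaccard_similarity <- function(sets) {
  n <- length(sets)
  s <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    s[i, i] <- 1
    if (i < n) for (j in seq((i + 1), n)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      s[i, j] <- s[j, i] <- if (uni == 0) 0 else inter / uni
    }
  }
  s
}

#' Affinity propagation clustering over a similarity matrix
#'
#' Message-passing exemplar clustering (responsibility/availability updates
#' with damping). Deterministic: symmetry between identical items is broken
#' by a fixed index-dependent perturbation subtracted from the off-diagonal
#' similarities, so items never merge on ties alone.
#'
#' @param s Square similarity matrix.
#' @param preference Self-similarity (exemplar propensity) assigned to every
#'   item; default is the median off-diagonal similarity.
#' @param damping Update damping factor in \[0.5, 1).
#' @param max_iter Maximum message-passing iterations.
#' @param conv_iter Iterations with an unchanged exemplar set required to
#'   declare convergence.
#' @return A list: `exemplars` (integer indices), `assignment` (exemplar
#'   index per item), `converged` (logical).
#' @export
affinity_propagation <- function(s, preference = NULL, damping = 0.5,
                                 max_iter = 500, conv_iter = 50) {
  n <- nrow(s)
  if (n == 1)
    return(list(exemplars = 1L, assignment = 1L, converged = TRUE))
  off <- s[row(s) != col(s)]
  if (is.null(preference)) preference <- stats::median(off)
  diag(s) <- preference
  # deterministic tie-breaking: tiny index-dependent penalty off-diagonal
  eps <- 1e-9 * max(1, max(abs(s)))
  jit <- outer(seq_len(n), seq_len(n),
               function(i, k) (i + n * k) / (n * (n + 1)))
  s <- s - eps * jit * (row(s) != col(s))

  r <- matrix(0, n, n); a <- matrix(0, n, n)
  stable <- 0L; last <- integer(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    # responsibilities
    as_ <- a + s
    max1 <- apply(as_, 1, max)
    which1 <- max.col(as_, ties.method = "first")
    max2 <- vapply(seq_len(n), function(i) {
      max(as_[i, -which1[i]])
    }, numeric(1))
    rnew <- s - max1
    rnew[cbind(seq_len(n), which1)] <- s[cbind(seq_len(n), which1)] - max2
    r <- damping * r + (1 - damping) * rnew
    # availabilities
    rp <- pmax(r, 0); diag(rp) <- diag(r)
    colsum <- colSums(rp)   # r(k,k) + sum of positive off-diagonal resps
    anew <- matrix(colsum, n, n, byrow = TRUE) - rp
    anew[anew > 0] <- 0
    diag(anew) <- colsum - diag(r)
    a <- damping * a + (1 - damping) * anew
    ex <- unname(which(diag(a) + diag(r) >= 0))
    if (identical(ex, last)) stable <- stable + 1L else stable <- 0L
    last <- ex
    if (stable >= conv_iter && length(ex) > 0) { converged <- TRUE; break }
  }
  ex <- last
  if (length(ex) == 0) {
    warning("affinity propagation did not identify exemplars; flagging all items",
            call. = FALSE)
    return(list(exemplars = seq_len(n), assignment = seq_len(n),
                converged = FALSE))
  }
  assign_to <- vapply(seq_len(n), function(i) {
    if (i %in% ex) return(i)
    ex[which.max(s[i, ex])]
  }, integer(1))
  list(exemplars = ex, assignment = assign_to, converged = converged)
}

#' Redundancy reduction of enriched sets by affinity propagation
#'
#' Clusters the significant gene sets by Jaccard similarity of their
#' members (within the universe) and flags one exemplar per cluster, as a
#' way to collapse near-duplicate pathway annotations.
#'
#' @param results Data.frame from [fisher_ora()].
#' @param collection The `gene_set_collection` (or named member list) the
#'   results came from.
#' @param universe Background used for the ORA; `NULL` uses raw member sets.
#' @param damping,preference,max_iter Passed to [affinity_propagation()].
#' @return `results` with a logical `is_exemplar` column (FALSE for
#'   non-significant sets) and attribute `clusters` mapping each significant
#'   set to its exemplar set ID.
#' @export
affinity_propagation_reduce <- function(results, collection, universe = NULL,
                                        damping = 0.5, preference = NULL,
                                        max_iter = 500) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  sig <- results$set_id[results$significant]
  results$is_exemplar <- FALSE
  if (length(sig) == 0) {
    attr(results, "clusters") <- stats::setNames(character(0), character(0))
    return(results)
  }
  members <- lapply(sets[sig], function(m) {
    if (is.null(universe)) m else intersect(m, universe)
  })
  ap <- affinity_propagation(jaccard_similarity(members), damping = damping,
                             preference = preference, max_iter = max_iter)
  exemplar_ids <- sig[ap$exemplars]
  results$is_exemplar <- results$set_id %in% exemplar_ids
  attr(results, "clusters") <- stats::setNames(sig[ap$assignment], sig)
  results
}
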