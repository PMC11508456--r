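#' Per-proteoform log2 mean fold change (case over control)
#'
#' The fold change is the ratio of the case group-mean abundance to the
#' control group-mean abundance, reported on the log2 scale. A pseudocount
#' is added to both means so that proteoforms undetected in one group do
#' not produce infinities; the default is half the smallest positive value
#' in the matrix.
#'
#' @param x An [abundance_matrix].
#' @param pseudocount Nonnegative value added to both group means; `NULL`
#'   (default) uses half the smallest positive abundance in `x`.
#' @return Named numeric vector of log2 fold changes, one per proteoform.
#' @export
log2_fold_change <- function(x, pseudocount = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (is.null(pseudocount)) {
    pos <- x$values[x$values > 0]
    pseudocount <- if (length(pos)) min(pos) / 2 else 0
  }
  if (pseudocount < 0) stop("`pseudocount` must be nonnegative", call. = FALSE)
  m_case <- rowMeans(x$values[, x$groups == "case", drop = FALSE])
  m_ctrl <- rowMeans(x$values[, x$groups == "control", drop = FALSE])
  fc <- log2((m_case + pseudocount) / (m_ctrl + pseudocount))
  if (any(!is.finite(fc)))
    warning("non-finite log2 fold changes (zero group mean with zero pseudocount)",
            call. = FALSE)
  stats::setNames(fc, rownames(x$values))
}

#' Wilcoxon rank-sum p-values per proteoform
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of case against control
#' abundances for each row. The exact null distribution is used when the
#' combined sample size is at most `exact_max` (default 30, covering the cohort) and the row has no ties;
#' otherwise the normal approximation with tie and continuity correction is
#' used. Constant rows (identical value in every sample) get p = 1.
#'
#' @param x An [abundance_matrix] with at least 2 samples per group.
#' @param exact_max Largest combined n for which the exact distribution is
#'   used (default 30).
#' @return Named numeric vector of two-sided p-values.
#' @export
wilcoxon_rank_sum <- function(x, exact_max = 30) {
  stopifnot(inherits(x, "abundance_matrix"))
  case <- x$groups == "case"
  if (sum(case) < 2 || sum(!case) < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  n_all <- ncol(x$values)
  p <- apply(x$values, 1, function(v) {
    a <- v[case]; b <- v[!case]
    if (max(v) == min(v)) return(1)
    has_ties <- anyDuplicated(v) > 0
    exact <- (n_all <= exact_max) && !has_ties
    suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
  })
  stats::setNames(pmin(p, 1), rownames(x$values))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a p-value vector; output order matches input order
#' and values are capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR q-values) in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Univariate differential abundance table
#'
#' Runs [log2_fold_change()], [wilcoxon_rank_sum()] and [bh_adjust()] and
#' applies the joint selection gate: a proteoform is selected when its fold
#' change magnitude reaches `fc_threshold` (a ratio; 1.3 means a 30\%
#' difference in either direction) and its FDR is below `alpha`.
#'
#' @param x An [abundance_matrix].
#' @param fc_threshold Fold-change gate as a ratio, >= 1 (default 1.3). With
#'   `fc_scale = "ratio"` the gate is |log2FC| >= log2(fc_threshold); with
#'   `fc_scale = "log2"` the threshold is interpreted directly on the log2
#'   scale (|log2FC| >= fc_threshold).
#' @param alpha FDR cutoff; selection requires fdr < alpha (strict).
#' @param pseudocount Passed to [log2_fold_change()].
#' @param fc_scale Either "ratio" (default) or "log2"; see `fc_threshold`.
#' @return A data.frame with columns `accession`, `log2fc`, `pvalue`, `fdr`,
#'   `selected`, ordered as the input rows, with attributes `n_up`/`n_down`
#'   (selected proteoforms with positive/negative log2FC).
#' @export
univariate_table <- function(x, fc_threshold = 1.3, alpha = 0.05,
                             pseudocount = NULL,
                             fc_scale = c("ratio", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (fc_threshold < 1 && fc_scale == "ratio")
    stop("`fc_threshold` must be at least 1 on the ratio scale", call. = FALSE)
  lfc <- log2_fold_change(x, pseudocount)
  p <- wilcoxon_rank_sum(x)
  fdr <- bh_adjust(p)
  res <- data.frame(accession = rownames(x$values), log2fc = unname(lfc),
                    pvalue = unname(p), fdr = unname(fdr),
                    stringsAsFactors = FALSE)
  select_univariate(res, fc_threshold = fc_threshold, alpha = alpha,
                    fc_scale = fc_scale)
}

#' Apply the joint fold-change / FDR selection gate
#'
#' @param results Data.frame with columns `accession`, `log2fc`, `fdr`.
#' @inheritParams univariate_table
#' @return `results` with a logical `selected` column and attributes `n_up`
#'   and `n_down` counting selected rows by log2FC sign.
#' @export
select_univariate <- function(results, fc_threshold = 1.3, alpha = 0.05,
                              fc_scale = c("ratio", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (fc_scale == "ratio") {
    if (fc_threshold < 1)
      stop("`fc_threshold` must be at least 1 on the ratio scale",
           call. = FALSE)
    lfc_gate <- log2(fc_threshold)
  } else {
    lfc_gate <- fc_threshold
  }
  results$selected <- abs(results$log2fc) >= lfc_gate & results$fdr < alpha
  attr(results, "n_up") <- sum(results$selected & results$log2fc > 0)
  attr(results, "n_down") <- sum(results$selected & results$log2fc < 0)
  results
}
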