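#' Fit a (sparse) PLS discriminant analysis model
#'
#' Supervised latent-component classifier for two-group abundance matrices.
#' The sample-by-protein matrix is column-wise autoscaled (mean 0, SD 1 by
#' default) and the group membership is dummy-coded as a single centered
#' indicator. Each component's loading vector is the dominant eigenvector of
#' the outer product of the protein-group cross-covariance -- for a single
#' response column this is the normalized cross-covariance vector itself --
#' optionally soft-thresholded so that only `keep_per_component` proteins
#' carry nonzero weight. Scores are the loading-weighted sums of the scaled
#' abundances (for component 1, S_j = sum_i u_i1 r_ij); both the predictor
#' matrix and the response are deflated between components.
#'
#' @param x An [abundance_matrix] (proteins x samples).
#' @param n_components Number of latent components, between 1 and
#'   min(n_samples - 1, n_proteins).
#' @param keep_per_component Number of proteins retained (nonzero loading)
#'   per component via soft thresholding; `NULL` fits the dense PLS-DA.
#' @param center,scale. Column-wise centering/unit-variance scaling of the
#'   sample-by-protein matrix before fitting (both default `TRUE`;
#'   zero-variance columns are left unscaled).
#' @return An object of class `splsda_model`: `loadings` (proteins x
#'   components, unit-norm columns), `scores` (samples x components),
#'   `eigenvalues` (per-component singular value of the cross-covariance),
#'   `variance_explained` (fraction of the scaled matrix variance per
#'   component), `x_loadings`, `y_loadings`, `center`, `scale`, `groups`.
#' @export
fit_splsda <- function(x, n_components = 2, keep_per_component = NULL,
                       center = TRUE, scale. = TRUE) {
  stopifnot(inherits(x, "abundance_matrix"))
  xs <- t(x$values)                      # samples x proteins
  n <- nrow(xs); p <- ncol(xs)
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("`n_components` must lie in [1, min(n_samples - 1, n_proteins)]",
         call. = FALSE)
  ctr <- if (center) colMeans(xs) else rep(0, p)
  xs <- sweep(xs, 2, ctr)
  scl <- rep(1, p)
  if (scale.) {
    scl <- apply(xs, 2, stats::sd)
    scl[scl == 0] <- 1
    xs <- sweep(xs, 2, scl, "/")
  }
  y <- as.numeric(x$groups == "case")
  y <- y - mean(y)

  r0 <- xs
  u <- matrix(0, p, n_components, dimnames = list(colnames(xs), NULL))
  tt <- matrix(0, n, n_components, dimnames = list(rownames(xs), NULL))
  pp <- matrix(0, p, n_components)
  q <- numeric(n_components)
  d <- numeric(n_components)
  for (h in seq_len(n_components)) {
    cvec <- drop(crossprod(xs, y))
    if (!is.null(keep_per_component) && keep_per_component < p) {
      thr <- sort(abs(cvec), decreasing = TRUE)[keep_per_component + 1L]
      cvec <- sign(cvec) * pmax(abs(cvec) - thr, 0)
    }
    d[h] <- sqrt(sum(cvec^2))
    if (d[h] < .Machine$double.eps^0.5)
      stop("degenerate fit: no covariance between abundances and groups",
           call. = FALSE)
    w <- cvec / d[h]
    th <- drop(xs %*% w)
    tss <- sum(th^2)
    ph <- drop(crossprod(xs, th)) / tss
    qh <- sum(th * y) / tss
    xs <- xs - tcrossprod(th, ph)
    y <- y - th * qh
    u[, h] <- w; tt[, h] <- th; pp[, h] <- ph; q[h] <- qh
  }
  ve <- vapply(seq_len(n_components), function(h) {
    coef <- drop(crossprod(r0, tt[, h])) / sum(tt[, h]^2)
    sum(tcrossprod(tt[, h], coef)^2) / sum(r0^2)
  }, numeric(1))
  structure(list(loadings = u, scores = tt, eigenvalues = d,
                 variance_explained = ve, x_loadings = pp, y_loadings = q,
                 center = ctr, scale = scl, groups = x$groups,
                 keep_per_component = keep_per_component),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("splsda_model: %d proteins, %d samples, %d component(s)\n",
              nrow(x$loadings), nrow(x$scores), ncol(x$loadings)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-component fraction of matrix variance explained
#'
#' Fraction of the total variance of the autoscaled abundance matrix
#' captured by regressing the matrix onto each component's score vector.
#' Scores are mutually orthogonal, so fractions are additive.
#'
#' @param model A fitted `splsda_model`.
#' @return Numeric vector of fractions in \[0, 1\], one per component.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "splsda_model"))
  model$variance_explained
}

#' Project new samples onto a fitted model and predict their group
#'
#' @param object A fitted `splsda_model`.
#' @param x An [abundance_matrix] over the same proteins.
#' @param ... Unused.
#' @return A list with `scores` (samples x components) and `class`
#'   (predicted "case"/"control" from the regression-on-scores rule).
#' @export
predict.splsda_model <- function(object, x, ...) {
  stopifnot(inherits(x, "abundance_matrix"))
  xs <- t(x$values[rownames(object$loadings), , drop = FALSE])
  xs <- sweep(sweep(xs, 2, object$center), 2, object$scale, "/")
  # weights in terms of the original (undeflated) matrix: R = U (P'U)^-1
  rmat <- object$loadings %*%
    solve(crossprod(object$x_loadings, object$loadings))
  scores <- xs %*% rmat
  yhat <- drop(scores %*% object$y_loadings)
  prior <- mean(object$groups == "case")
  cls <- ifelse(yhat + prior >= 0.5, "case", "control")
  list(scores = scores, class = stats::setNames(cls, rownames(xs)))
}

#' Choose the number of sPLS-DA components by cross-validated error
#'
#' Repeated stratified k-fold cross-validation; for each candidate component
#' count the balanced error rate (mean of the two per-group error rates) is
#' averaged over folds and repeats. Counts are accepted sequentially:
#' count h+1 replaces h only when the paired repeat-level improvement in
#' error exceeds its standard error across repeats (or a numeric `tol`
#' when given). Chance fluctuations rarely clear that bar, so a pure-noise
#' matrix returns 1 by parsimony.
#'
#' @param x An [abundance_matrix].
#' @param max_components Largest component count examined.
#' @param n_folds Folds per repeat; must not exceed the smaller group size.
#' @param n_repeats Cross-validation repeats.
#' @param seed Integer seed for fold assignment.
#' @param tol Improvement a further component must deliver to be accepted;
#'   `NULL` (default) requires the improvement to exceed its own standard
#'   error across repeats.
#' @return The chosen component count, with the per-count mean balanced
#'   error rates in attribute `ber`.
#' @export
select_n_components <- function(x, max_components = 5, n_folds = 5,
                                n_repeats = 10, seed = 1, tol = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (max_components < 1)
    stop("`max_components` must be at least 1", call. = FALSE)
  grp <- x$groups
  n_small <- min(table(grp))
  if (n_folds > n_small)
    stop("`n_folds` exceeds the smaller group size", call. = FALSE)
  max_components <- min(max_components,
                        ncol(x$values) - ceiling(ncol(x$values) / n_folds) - 1,
                        nrow(x$values))
  set.seed(seed)
  err <- matrix(NA_real_, n_repeats * n_folds, max_components)
  row <- 0L
  for (r in seq_len(n_repeats)) {
    fold <- stats::setNames(integer(length(grp)), names(grp))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    for (f in seq_len(n_folds)) {
      test_ids <- names(grp)[fold == f]
      train_ids <- setdiff(names(grp), test_ids)
      train <- abundance_matrix(x$values[, train_ids, drop = FALSE],
                                grp[train_ids])
      test <- abundance_matrix(x$values[, test_ids, drop = FALSE],
                               grp[test_ids])
      row <- row + 1L
      for (h in seq_len(max_components)) {
        fit <- try(fit_splsda(train, n_components = h), silent = TRUE)
        if (inherits(fit, "try-error")) next
        pred <- predict(fit, test)$class
        ber <- mean(vapply(c("case", "control"), function(g) {
          in_g <- grp[test_ids] == g
          if (!any(in_g)) return(NA_real_)
          mean(pred[in_g] != g)
        }, numeric(1)), na.rm = TRUE)
        err[row, h] <- ber
      }
    }
  }
  ber <- colMeans(err, na.rm = TRUE)
  rep_id <- rep(seq_len(n_repeats), each = n_folds)
  rep_means <- apply(err, 2, function(e) tapply(e, rep_id, mean, na.rm = TRUE))
  rep_means <- matrix(rep_means, nrow = n_repeats)
  chosen <- 1L
  while (chosen < max_components) {
    d <- rep_means[, chosen] - rep_means[, chosen + 1L]
    d <- d[is.finite(d)]
    gate <- if (!is.null(tol)) tol
            else if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0.01
    if (mean(d) > gate) chosen <- chosen + 1L else break
  }
  structure(chosen, ber = ber)
}

#' Recursive feature elimination driven by component-1 loadings
#'
#' Repeatedly fits the (s)PLS-DA on the current protein set and removes the
#' protein with the smallest absolute loading on component 1 (ties broken
#' towards the lexicographically smallest accession), until
#' `ceiling(target_fraction * initial count)` proteins remain. The matrix is
#' re-autoscaled before every fit. A chunk size > 1 removes that many
#' lowest-loading proteins per iteration (never overshooting the target).
#'
#' @param x An [abundance_matrix].
#' @param n_components Components per fit (elimination always uses
#'   component 1).
#' @param target_fraction Fraction of the initial protein count to retain,
#'   in (0, 1).
#' @param chunk Proteins removed per iteration (default 1).
#' @param keep_per_component Optional sparsity per fit; see [fit_splsda()].
#' @return An object of class `rfe_trace`: `eliminated` (data.frame
#'   `iteration`, `accession`, `abs_loading` in elimination order),
#'   `retained` (character vector), `n_initial`, `n_target`, `final_model`
#'   (fit on the retained set), `variance_explained_final`.
#' @export
rfe <- function(x, n_components = 2, target_fraction = 0.05, chunk = 1,
                keep_per_component = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("`target_fraction` must lie in (0, 1)", call. = FALSE)
  p0 <- nrow(x$values)
  n_target <- ceiling(target_fraction * p0)
  if (n_target < 1)
    stop("`target_fraction` retains fewer than one protein", call. = FALSE)
  if (chunk < 1) stop("`chunk` must be at least 1", call. = FALSE)
  current <- x
  elim <- vector("list", p0 - n_target)
  n_elim <- 0L
  iter <- 0L
  while (nrow(current$values) > n_target) {
    iter <- iter + 1L
    fit <- fit_splsda(current, n_components = n_components,
                      keep_per_component = keep_per_component)
    au <- abs(fit$loadings[, 1])
    ord <- order(au, rownames(fit$loadings))
    n_drop <- min(chunk, nrow(current$values) - n_target)
    drop_idx <- ord[seq_len(n_drop)]
    elim[seq(n_elim + 1L, n_elim + n_drop)] <- lapply(drop_idx, function(i) {
      data.frame(iteration = iter, accession = rownames(fit$loadings)[i],
                 abs_loading = unname(au[i]), stringsAsFactors = FALSE)
    })
    n_elim <- n_elim + n_drop
    keep <- rownames(current$values)[-drop_idx]
    current <- abundance_matrix(current$values[keep, , drop = FALSE],
                                current$groups)
  }
  final <- fit_splsda(current, n_components = n_components,
                      keep_per_component = keep_per_component)
  structure(list(eliminated = do.call(rbind, elim),
                 retained = rownames(current$values),
                 n_initial = p0, n_target = n_target,
                 final_model = final,
                 variance_explained_final = final$variance_explained),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf("rfe_trace: %d -> %d proteins (%d eliminated)\n",
              x$n_initial, length(x$retained), nrow(x$eliminated)))
  cat("final variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained_final),
            collapse = ", "), "\n")
  invisible(x)
}
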