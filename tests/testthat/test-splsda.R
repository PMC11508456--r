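test_that("component-1 scores are loading-weighted sums of scaled abundances", {
  sim <- simulate_abundance(synthetic_config(n_proteins = 100, n_markers = 10,
                                             seed = 31))
  fit <- fit_splsda(sim$matrix, n_components = 2)
  xs <- scale(t(sim$matrix$values))
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  expect_lt(max(abs(xs %*% fit$loadings[, 1] - fit$scores[, 1])), 1e-8)
  expect_equal(unname(colSums(fit$loadings^2)), rep(1, 2))
})

test_that("dense single-component loading matches the eigendecomposition oracle", {
  set.seed(5)
  v <- matrix(abs(rnorm(6 * 4, 10, 3)), 6, 4)
  am <- tiny_abundance(v, 2, 2)
  fit <- fit_splsda(am, n_components = 1)
  # cross-covariance of scaled columns with the centered group indicator,
  # computed with explicit loops
  xs <- scale(t(v))
  y <- c(1, 1, 0, 0) - 0.5
  cvec <- numeric(6)
  for (i in 1:6) for (j in 1:4) cvec[i] <- cvec[i] + xs[j, i] * y[j]
  ev <- eigen(outer(cvec, cvec))$vectors[, 1]
  cross <- abs(sum(fit$loadings[, 1] * ev))
  expect_equal(cross, 1, tolerance = 1e-10)
  expect_equal(fit$eigenvalues[1], sqrt(sum(cvec^2)))
})

test_that("sparsity keeps only the discriminating protein", {
  v <- rbind(c(10, 11, 10.5, 1, 1.2, 0.9),      # separates the groups
             c(5.1, 4.9, 5.2, 5.0, 4.8, 5.15))  # pure noise
  am <- tiny_abundance(v, 3, 3)
  fit <- fit_splsda(am, n_components = 1, keep_per_component = 1)
  expect_equal(unname(abs(fit$loadings[, 1]) > 0), c(TRUE, FALSE))
})

test_that("degenerate and ill-sized fits are rejected", {
  v <- matrix(5, 4, 6, dimnames = list(paste0("P", 1:4), paste0("s", 1:6)))
  am <- abundance_matrix(v, rep(c("case", "control"), each = 3))
  expect_error(fit_splsda(am, 1), "degenerate")
  sim <- simulate_abundance(synthetic_config(n_proteins = 20, seed = 1))
  expect_error(fit_splsda(sim$matrix, n_components = 40), "n_components")
})

test_that("variance explained matches a direct residual-sum-of-squares oracle", {
  set.seed(9)
  v <- matrix(abs(rnorm(80, 50, 10)), 10, 8)
  am <- tiny_abundance(v, 4, 4)
  fit <- fit_splsda(am, n_components = 3)
  xs <- scale(t(v))
  total <- sum(xs^2)
  for (h in 1:3) {
    t_h <- fit$scores[, h]
    fitted <- t_h %*% t(drop(crossprod(xs, t_h)) / sum(t_h^2))
    rss <- sum((xs - fitted)^2)
    expect_equal(fit$variance_explained[h], (total - rss) / total,
                 tolerance = 1e-10)
  }
  # scores are orthogonal, so fractions are additive and bounded
  expect_lt(max(abs(crossprod(fit$scores) -
                      diag(colSums(fit$scores^2)))), 1e-8)
  expect_lte(sum(fit$variance_explained), 1 + 1e-12)

  # rank-1 matrix, one component -> everything explained
  v1 <- outer(abs(rnorm(5)) + 1, abs(rnorm(6)) + 1)
  am1 <- tiny_abundance(v1, 3, 3)
  f1 <- fit_splsda(am1, n_components = 1)
  expect_equal(f1$variance_explained[1], 1, tolerance = 1e-10)
})

test_that("RFE obeys the ceil stopping rule and records a complete trace", {
  sim <- simulate_abundance(synthetic_config(n_proteins = 100, n_markers = 10,
                                             seed = 41))
  tr <- rfe(sim$matrix, n_components = 2, target_fraction = 0.05)
  expect_length(tr$retained, 5)            # ceil(0.05 * 100)
  expect_equal(nrow(tr$eliminated), 95)
  ids <- c(tr$eliminated$accession, tr$retained)
  expect_setequal(ids, rownames(sim$matrix$values))
  expect_false(anyDuplicated(ids) > 0)
  # ceil rounding: 130 proteins at 5% -> 7 retained
  sim2 <- simulate_abundance(synthetic_config(n_proteins = 130, n_markers = 10,
                                              seed = 41))
  expect_length(rfe(sim2$matrix, 1, 0.05)$retained, ceiling(0.05 * 130))
  expect_error(rfe(sim$matrix, 2, target_fraction = 1.2), "target_fraction")
})

test_that("chunked elimination reaches the same retained count", {
  sim <- simulate_abundance(synthetic_config(n_proteins = 90, n_markers = 10,
                                             seed = 43))
  tr1 <- rfe(sim$matrix, 1, 0.1, chunk = 1)
  tr7 <- rfe(sim$matrix, 1, 0.1, chunk = 7)
  expect_length(tr7$retained, length(tr1$retained))
  expect_lt(max(tr7$eliminated$iteration), max(tr1$eliminated$iteration))
})

test_that("a dominant discriminant protein survives every elimination", {
  for (s in 1:20) {
    sim <- simulate_abundance(synthetic_config(
      n_proteins = 40, n_markers = 1, effect_log2fc = 4, noise_sd = 0.5,
      missing_rate = 0, seed = s))
    tr <- rfe(sim$matrix, n_components = 1, target_fraction = 0.1)
    expect_true(sim$truth$marker_ids %in% tr$retained)
  }
})

test_that("permuted labels leave markers no more retained than chance", {
  hits <- vapply(1:12, function(s) {
    sim <- simulate_abundance(synthetic_config(
      n_proteins = 100, n_markers = 20, effect_log2fc = 2, seed = s))
    set.seed(1000 + s)
    x <- abundance_matrix(sim$matrix$values, sample(sim$matrix$groups))
    tr <- rfe(x, n_components = 1, target_fraction = 0.1)
    mean(sim$truth$marker_ids %in% tr$retained)
  }, numeric(1))
  # retained fraction is 10%; planted markers should hover around it
  expect_lt(mean(hits), 0.1 + 3 * sd(hits) / sqrt(length(hits)))
})

test_that("cross-validated component selection is parsimonious", {
  noise <- simulate_abundance(synthetic_config(
    n_proteins = 80, n_markers = 0, effect_log2fc = 0, seed = 3))
  k_noise <- select_n_components(noise$matrix, max_components = 4,
                                 n_repeats = 10, seed = 1)
  expect_equal(as.integer(k_noise), 1L)
  one_axis <- simulate_abundance(synthetic_config(
    n_proteins = 80, n_markers = 8, effect_log2fc = 3, noise_sd = 0.5,
    seed = 3))
  k_sig <- select_n_components(one_axis$matrix, max_components = 4,
                               n_repeats = 10, seed = 1)
  expect_lte(as.integer(k_sig), 2L)
  expect_error(select_n_components(noise$matrix, n_folds = 50), "n_folds")
})
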