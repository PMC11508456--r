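# Independent brute-force oracles used to check the package's statistics.
# These deliberately share no code path with the implementation.

# Benjamini-Hochberg step-up, written as the literal definition:
# q_(i) = min_{j >= i} min(m * p_(j) / j, 1), reported in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data only; feasible for small groups).
wilcox_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(n1 + n2, n1)
  u_null <- apply(picks, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lower <- mean(u_null <= u_obs)
  upper <- mean(u_null >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Null distribution of the rank-sum W = sum of case ranks for group sizes
# (n1, n2), by dynamic programming over subsets of ranks 1..(n1+n2):
# counts[k+1, w+1] = number of k-subsets with rank sum w.
ranksum_null_counts <- function(n1, n2) {
  n <- n1 + n2
  wmax <- sum((n - n1 + 1):n)
  counts <- matrix(0, n1 + 1, wmax + 1)
  counts[1, 1] <- 1
  for (rank_val in seq_len(n)) {
    for (k in min(rank_val, n1):1) {
      nz <- which(counts[k, ] > 0)
      if (length(nz))
        counts[k + 1, nz + rank_val] <- counts[k + 1, nz + rank_val] +
          counts[k, nz]
    }
  }
  counts[n1 + 1, ]   # index w+1 = count of n1-subsets with rank sum w
}

# Upper-tail hypergeometric P(X >= k) as an explicit sum of counts of
# favourable draws over all C(N, n) equally likely draws.
hyper_upper_oracle <- function(k, m, N, n) {
  js <- k:min(m, n)
  js <- js[js >= max(0, n - (N - m))]
  if (length(js) == 0) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# Same tail by literal enumeration of every draw (tiny N only).
hyper_enum_oracle <- function(k, m, N, n) {
  in_set <- seq_len(m)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% in_set) >= k))
}

# Nested-loop reference for network pruning: both endpoints in the input
# list, no self-loops, unordered-unique edges, degree-0 nodes dropped.
prune_oracle <- function(id_a, id_b, input_set) {
  seen <- character(0)
  edges <- list()
  for (i in seq_along(id_a)) {
    a <- id_a[i]; b <- id_b[i]
    if (!(a %in% input_set) || !(b %in% input_set)) next
    if (a == b) next
    key <- paste(min(a, b), max(a, b), sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    edges[[length(edges) + 1]] <- c(min(a, b), max(a, b))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), 0, 2)
  nodes <- sort(unique(as.vector(edges)))
  list(edges = edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
       nodes = nodes)
}

# Small deterministic abundance fixture: explicit values, no randomness.
tiny_abundance <- function(values, n_case, n_control,
                           accessions = sprintf("P%05d", seq_len(nrow(values)))) {
  dimnames(values) <- list(
    accessions,
    c(sprintf("case_%02d", seq_len(n_case)),
      sprintf("control_%02d", seq_len(n_control))))
  abundance_matrix(values, rep(c("case", "control"), c(n_case, n_control)))
}
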