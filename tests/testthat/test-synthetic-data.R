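test_that("generator reproduces the cohort shape and is byte-deterministic", {
  cfg <- synthetic_config(n_proteins = 120, n_markers = 10, seed = 42)
  sim1 <- simulate_abundance(cfg)
  expect_equal(dim(sim1$matrix$values), c(120, 30))
  expect_equal(sum(sim1$matrix$groups == "case"), 10)
  expect_equal(sum(sim1$matrix$groups == "control"), 20)
  expect_true(all(sim1$matrix$values >= 0))
  expect_true(all(sim1$truth$marker_ids %in% rownames(sim1$matrix$values)))
  expect_true(all(unlist(sim1$truth$planted_edges) %in%
                    sub("-.*$", "", rownames(sim1$matrix$values))))

  sim2 <- simulate_abundance(cfg)
  f1 <- tempfile(); f2 <- tempfile(); a1 <- tempfile(); a2 <- tempfile()
  write_abundance(sim1$matrix, f1, a1)
  write_abundance(sim2$matrix, f2, a2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(a1), readLines(a2))
  unlink(c(f1, f2, a1, a2))

  tmp <- tempfile(); ann <- tempfile()
  write_abundance(sim1$matrix, tmp, ann)
  rt <- read_abundance(tmp, ann)
  expect_equal(rt$values, sim1$matrix$values)
  expect_identical(rt$groups, sim1$matrix$groups)
  unlink(c(tmp, ann))
})

test_that("isoform bookkeeping matches the configured fraction", {
  for (frac in c(0, 0.1, 0.25)) {
    cfg <- synthetic_config(n_proteins = 200, isoform_fraction = frac,
                            seed = 5)
    acc <- rownames(simulate_abundance(cfg)$matrix$values)
    expect_equal(sum(grepl("-", acc, fixed = TRUE)), round(frac * 200))
    # every isoform's base accession is itself a generated row
    iso <- acc[grepl("-", acc, fixed = TRUE)]
    expect_true(all(sub("-.*$", "", iso) %in% acc))
  }
})

test_that("planted markers carry the configured effect; zero effect is null", {
  # Monte-Carlo over seeds: mean empirical |log2FC| of markers ~ planted 2.0
  lfcs <- vapply(1:20, function(s) {
    sim <- simulate_abundance(synthetic_config(
      n_proteins = 150, n_markers = 30, effect_log2fc = 2,
      missing_rate = 0, seed = s))
    lfc <- log2_fold_change(sim$matrix)
    mean(abs(lfc[sim$truth$marker_ids]))
  }, numeric(1))
  se <- sd(lfcs) / sqrt(length(lfcs))
  expect_lt(abs(mean(lfcs) - 2), 3 * se)

  # zero effect: marker |log2FC| distributed like non-markers
  # (independent rows so the two-sample comparison is valid)
  sim0 <- simulate_abundance(synthetic_config(
    n_proteins = 400, n_markers = 40, effect_log2fc = 0,
    block_rho = 0, missing_rate = 0, seed = 9))
  lfc0 <- log2_fold_change(sim0$matrix)
  is_marker <- names(lfc0) %in% sim0$truth$marker_ids
  ks <- suppressWarnings(ks.test(abs(lfc0[is_marker]), abs(lfc0[!is_marker])))
  expect_gt(ks$p.value, 0.01)
})

test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_markers = 50, n_proteins = 10), "n_markers")
  expect_error(synthetic_config(block_rho = 1), "block_rho")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  expect_error(synthetic_config(isoform_fraction = 1.2), "isoform_fraction")
})

test_that("interactome generator plants edges and flags filter fodder", {
  sim <- simulate_abundance(synthetic_config(n_proteins = 60, n_markers = 12,
                                             seed = 21))
  mt <- tempfile(fileext = ".mitab")
  rows <- simulate_interactome(sim$truth, rownames(sim$matrix$values), mt,
                               background_edge_prob = 0.01,
                               decoy_taxid_fraction = 0.1, seed = 21)
  rec <- read_mitab(mt)
  expect_equal(nrow(rec), nrow(rows))
  # taxonomy filter removes exactly the decoy rows
  kept <- filter_records(rec, taxid = 9606, protein_only = FALSE)
  expect_setequal(kept$source_line, which(rows$kind != "decoy_taxid"))
  # planted edges survive the full prune
  net <- prune_to_input(filter_records(rec),
                        sub("-.*$", "", rownames(sim$matrix$values)))
  pl <- sim$truth$planted_edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(pl$a, pl$b) %in% key(net$edges$a, net$edges$b)))
  expect_error(simulate_interactome(sim$truth, character(0), mt),
               "non-empty")
  unlink(mt)
})

test_that("background-free interactome prunes to exactly the planted path", {
  truth <- list(marker_ids = sprintf("M%02d", 1:6),
                direction = setNames(rep("up", 6), sprintf("M%02d", 1:6)),
                planted_edges = data.frame(a = sprintf("M%02d", 1:5),
                                           b = sprintf("M%02d", 2:6)),
                planted_set_id = "PATHWAY_PLANTED")
  mt <- tempfile(fileext = ".mitab")
  simulate_interactome(truth, sprintf("M%02d", 1:6), mt,
                       background_edge_prob = 0, decoy_taxid_fraction = 0,
                       nonprotein_fraction = 0, duplicate_fraction = 0.5,
                       n_self_loops = 2, seed = 3)
  net <- prune_to_input(filter_records(read_mitab(mt)), sprintf("M%02d", 1:6))
  expect_equal(net$n_edges, 5)
  expect_equal(net$n_nodes, 6)
  # only self-loops and no planted edges -> empty network
  truth0 <- truth
  truth0$planted_edges <- truth$planted_edges[0, ]
  simulate_interactome(truth0, sprintf("M%02d", 1:6), mt,
                       background_edge_prob = 0, decoy_taxid_fraction = 0,
                       nonprotein_fraction = 0, n_self_loops = 3, seed = 3)
  net0 <- prune_to_input(filter_records(read_mitab(mt)), sprintf("M%02d", 1:6))
  expect_equal(net0$n_nodes, 0)
  expect_equal(net0$n_edges, 0)
  unlink(mt)
})

test_that("gene-set generator plants one marker-enriched set", {
  sim <- simulate_abundance(synthetic_config(n_proteins = 200, n_markers = 20,
                                             seed = 13))
  gmt <- tempfile(fileext = ".gmt")
  simulate_gene_sets(sim$truth, rownames(sim$matrix$values), gmt,
                     n_sets = 25, seed = 13)
  coll <- read_gmt(gmt)
  expect_length(coll$sets, 25)
  expect_true(sim$truth$planted_set_id %in% names(coll$sets))
  marker_bases <- unique(sub("-.*$", "", sim$truth$marker_ids))
  res <- fisher_ora(marker_bases, coll)
  expect_equal(res$set_id[1], sim$truth$planted_set_id)
  expect_equal(min(res$fdr), res$fdr[res$set_id == sim$truth$planted_set_id])
  expect_error(simulate_gene_sets(sim$truth, sprintf("X%d", 1:5), gmt,
                                  n_sets = 2, set_size_range = c(2, 10)),
               "universe")
  unlink(gmt)
})

test_that("ground truth survives a JSON round trip", {
  sim <- simulate_abundance(synthetic_config(n_proteins = 80, n_markers = 8,
                                             seed = 2))
  p <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, p)
  rt <- read_ground_truth(p)
  expect_setequal(rt$marker_ids, sim$truth$marker_ids)
  expect_equal(rt$direction[sim$truth$marker_ids],
               sim$truth$direction[sim$truth$marker_ids])
  expect_equal(rt$planted_edges$a, sim$truth$planted_edges$a)
  expect_equal(rt$planted_set_id, sim$truth$planted_set_id)
  unlink(p)
})
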