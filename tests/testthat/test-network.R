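mitab_line <- function(a, b, tax_a = "taxid:9606(human)",
                       tax_b = "taxid:9606(human)",
                       type_a = "psi-mi:\"MI:0326\"(protein)",
                       type_b = "psi-mi:\"MI:0326\"(protein)",
                       ncol = 22) {
  f <- rep("-", ncol)
  f[1] <- a; f[2] <- b; f[10] <- tax_a; f[11] <- tax_b
  if (ncol >= 22) { f[21] <- type_a; f[22] <- type_b }
  paste(f, collapse = "\t")
}

test_that("MITAB parsing extracts base accessions and taxa", {
  p <- tempfile()
  writeLines(c(
    mitab_line("uniprotkb:P14618-2", "uniprotkb:P08107"),
    mitab_line("intact:EBI-123", "uniprotkb:Q99999",
               tax_b = "taxid:10090(mouse)"),
    mitab_line("uniprotkb:P1", "uniprotkb:P2", ncol = 15)), p)
  rec <- read_mitab(p)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$id_a[1], "P14618")      # isoform suffix stripped
  expect_false(rec$uniprot_a[2])           # non-uniprot kept, flagged
  expect_equal(rec$taxid_b[2], 10090L)
  expect_equal(rec$type_a[3], "unknown")   # 15-column core has no type
  expect_equal(rec$source_line, 1:3)

  writeLines(character(0), p)
  expect_equal(nrow(read_mitab(p)), 0)

  writeLines("uniprotkb:P1\tuniprotkb:P2\t-", p)
  expect_error(read_mitab(p), "line 1")
  unlink(p)
})

test_that("taxonomy and interactor-type filters keep the declared rows", {
  p <- tempfile()
  writeLines(c(
    mitab_line("uniprotkb:P1", "uniprotkb:P2"),
    mitab_line("uniprotkb:P1", "uniprotkb:P3",
               tax_b = "taxid:10090(mouse)"),
    mitab_line("uniprotkb:P2", "uniprotkb:P3",
               type_b = "psi-mi:\"MI:0250\"(gene)"),
    mitab_line("uniprotkb:P2", "uniprotkb:P4")), p)
  rec <- read_mitab(p)
  kept <- filter_records(rec)
  expect_equal(kept$source_line, c(1L, 4L))
  kept_any_type <- filter_records(rec, protein_only = FALSE)
  expect_equal(kept_any_type$source_line, c(1L, 3L, 4L))
  # all-9606 protein records pass unchanged
  expect_equal(filter_records(rec[c(1, 4), ]), rec[c(1, 4), ])
  unlink(p)
})

test_that("pruning matches the nested-loop reference on random instances", {
  set.seed(6)
  for (r in 1:100) {
    n_nodes <- sample(5:50, 1)
    nodes <- sprintf("N%02d", seq_len(n_nodes))
    n_rec <- sample(1:80, 1)
    id_a <- sample(nodes, n_rec, replace = TRUE)
    id_b <- sample(nodes, n_rec, replace = TRUE)
    input <- sample(nodes, sample(2:n_nodes, 1))
    rec <- data.frame(id_a = id_a, id_b = id_b, stringsAsFactors = FALSE)
    net <- prune_to_input(rec, input)
    oracle <- prune_oracle(id_a, id_b, input)
    expect_equal(net$nodes$accession, oracle$nodes)
    expect_equal(net$edges$a, unname(oracle$edges[, 1]))
    expect_equal(net$edges$b, unname(oracle$edges[, 2]))
  }
})

test_that("pruning is idempotent and removes hub-dependent leaves", {
  # star centered on a non-input hub: all edges vanish
  rec <- data.frame(id_a = rep("HUB", 5),
                    id_b = sprintf("L%d", 1:5), stringsAsFactors = FALSE)
  net <- prune_to_input(rec, sprintf("L%d", 1:5))
  expect_equal(net$n_nodes, 0)
  expect_equal(net$n_edges, 0)

  rec2 <- data.frame(
    id_a = c("A", "B", "A", "A", "C"),
    id_b = c("B", "A", "A", "C", "D"), stringsAsFactors = FALSE)
  net2 <- prune_to_input(rec2, c("A", "B", "C"))
  # re-pruning the pruned edge list changes nothing
  renet <- prune_to_input(
    data.frame(id_a = net2$edges$a, id_b = net2$edges$b), c("A", "B", "C"))
  expect_equal(renet$edges, net2$edges)
  expect_equal(renet$nodes, net2$nodes)
  # no invented edges: every pruned edge is a filtered record pair
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(net2$edges$a, net2$edges$b) %in%
                    key(rec2$id_a, rec2$id_b)))
  expect_error(prune_to_input(rec2, character(0)), "non-empty")
})

test_that("direction annotation matches log2FC signs and swaps under negation", {
  tab <- oscc_connected_proteins()
  edges <- data.frame(id_a = tab$accession[-1], id_b = tab$accession[-nrow(tab)])
  net <- prune_to_input(edges, tab$accession)
  net <- annotate_directions(net, tab)
  expect_equal(net$n_nodes, 48)
  expect_equal(net$n_up, 30)
  expect_equal(net$n_down, 18)

  flipped <- transform(tab, log2fc = -log2fc)
  net_f <- annotate_directions(net, flipped)
  expect_equal(net_f$n_up, 18)
  expect_equal(net_f$n_down, 30)

  expect_error(annotate_directions(net, tab[-1, ]), tab$accession[1])
})

test_that("network files round-trip through the writers", {
  tab <- oscc_connected_proteins()[1:6, ]
  edges <- data.frame(id_a = tab$accession[c(1, 2, 3)],
                      id_b = tab$accession[c(2, 3, 4)])
  net <- annotate_directions(prune_to_input(edges, tab$accession), tab)
  ef <- tempfile(); nf <- tempfile(); gf <- tempfile(fileext = ".graphml")
  write_network(net, ef, nf, gf)
  e <- read.delim(ef)
  expect_equal(nrow(e), 3)
  g <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_setequal(igraph::vertex_attr(g, "direction"), net$nodes$direction)
  unlink(c(ef, nf, gf))
})
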