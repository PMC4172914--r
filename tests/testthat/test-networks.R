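randomNetwork <- function(seed) {
  set.seed(seed)
  n_mir <- sample(3:10, 1)
  n_gene <- sample(5:30, 1)
  de <- data.frame(mirna_id = paste0("m", seq_len(n_mir)),
                   fold_change = 2^runif(n_mir, -6, 6))
  tm <- unique(data.frame(
    mirna = sample(de$mirna_id, n_mir * 6, replace = TRUE),
    gene = sample(paste0("g", seq_len(n_gene)), n_mir * 6, replace = TRUE)))
  list(net = mirnaGeneNetwork(de, tm), de = de, tm = tm)
}

test_that("miRNA-gene network edges mirror the target map", {
  de <- data.frame(mirna_id = c("m1", "m2", "m3"),
                   fold_change = c(8, 0.25, 4))
  tm <- data.frame(mirna = c("m1", "m1", "m2", "m4"),
                   gene = c("g1", "g2", "g1", "g9"))
  net <- mirnaGeneNetwork(de, tm)
  # m3 has no targets -> dropped; m4 is not differential -> absent
  expect_setequal(net@leftNodes$id, c("m1", "m2"))
  expect_setequal(net@rightNodes$id, c("g1", "g2"))
  expect_equal(nrow(net@edges), 3L)
  # weights are |log2 FC| of the miRNA: symmetric in orientation
  w <- net@edges$weight[net@edges$from == "m2"]
  expect_equal(w, abs(log2(0.25)))
  expect_equal(w, abs(log2(1 / 0.25)))
  # star graph: shared gene collects degree, each miRNA degree counts edges
  d <- degrees(net)
  expect_equal(unname(d["g1"]), 2L)
  expect_equal(unname(d["m1"]), 2L)
  expect_warning(mirnaGeneNetwork(de[3, ], tm), "empty network")
})

test_that("degrees satisfy the handshake identity and a brute-force recount", {
  for (seed in 1:100) {
    r <- randomNetwork(seed)
    e <- r$net@edges
    dl <- degrees(r$net, "left"); dr <- degrees(r$net, "right")
    expect_equal(sum(dl), nrow(e))
    expect_equal(sum(dr), nrow(e))
    expect_equal(sum(degrees(r$net)), 2L * nrow(e))
    # brute-force recount over the edge list
    for (v in sample(names(c(dl, dr)), 3))
      expect_equal(unname(c(dl, dr)[v]),
                   sum(e$from == v) + sum(e$to == v))
  }
})

test_that("hub ranking sorts by degree with lexicographic ties", {
  de <- data.frame(mirna_id = c("m1", "m2", "m3"),
                   fold_change = c(4, 8, 16))
  tm <- data.frame(mirna = c("m1", "m2", "m3"), gene = "hub")
  star <- mirnaGeneNetwork(de, tm)
  hubs <- rankHubs(star)
  expect_equal(hubs$id[1], "hub")
  expect_equal(hubs$degree[1], 3L)
  # all remaining degrees equal -> lexicographic order
  expect_equal(hubs$id[-1], c("m1", "m2", "m3"))
  expect_true(all(diff(hubs$degree) <= 0))
  expect_equal(nrow(rankHubs(star, topK = 2)), 2L)
  expect_error(rankHubs(star, topK = 0), "positive")
  # ranking equals a brute-force sort of recounted degrees
  r <- randomNetwork(7)
  got <- rankHubs(r$net)
  d <- degrees(r$net)
  expected <- names(d)[order(-d, names(d))]
  expect_equal(got$id, expected)
})

test_that("removing a miRNA removes exactly its degree in edges", {
  r <- randomNetwork(11)
  d <- degrees(r$net, "left")
  m <- names(d)[1]
  pruned <- mirnaGeneNetwork(r$de[r$de$mirna_id != m, ], r$tm)
  expect_equal(nrow(r$net@edges) - nrow(pruned@edges), unname(d[m]))
})

test_that("miRNA-GO network connects miRNAs to terms through shared genes", {
  de <- data.frame(mirna_id = c("m1", "m2"), fold_change = c(4, 0.25))
  tm <- data.frame(mirna = c("m1", "m1", "m2"),
                   gene = c("g1", "g2", "g3"))
  gsl <- geneSetList(list(t1 = c("g1", "g2"), t2 = c("g3", "g9")))
  # no significant terms -> empty network
  net0 <- mirnaGoNetwork(de, tm, character(0), gsl)
  expect_equal(nrow(net0@edges), 0L)
  # one miRNA with all targets inside one term: one edge, both degrees 1
  net1 <- mirnaGoNetwork(de[1, ], tm, "t1", gsl)
  expect_equal(nrow(net1@edges), 1L)
  expect_equal(unname(degrees(net1)), c(1L, 1L))
  # weight = shared genes x |log2 FC|
  expect_equal(net1@edges$weight, 2 * log2(4))
  net <- mirnaGoNetwork(de, tm, c("t1", "t2"), gsl)
  expect_equal(sort(net@edges$to), c("t1", "t2"))
})

test_that("planted term is well connected in the GO network", {
  sim <- simulateCtPanel(panelConfig(seed = 17))
  ann <- simulateAnnotations(rownames(sim$panel), sim$truth$de$mirna_id,
                             nGenes = 1000, nTerms = 40,
                             nPlantedTerms = 1, seed = 17)
  de <- data.frame(mirna_id = sim$truth$de$mirna_id,
                   fold_change = 2^sim$truth$de$log2fc,
                   direction = sim$truth$de$direction)
  net <- mirnaGoNetwork(de, ann$targetMap, names(geneSets(ann$geneSets)),
                        ann$geneSets)
  dr <- degrees(net, "right")
  expect_gte(unname(dr[ann$plantedTerms]), median(dr))
})

test_that("network exports are written and igraph agrees on structure", {
  r <- randomNetwork(23)
  g <- asIgraph(r$net)
  expect_equal(igraph::gorder(g),
               nrow(r$net@leftNodes) + nrow(r$net@rightNodes))
  expect_equal(igraph::gsize(g), nrow(r$net@edges))
  d_ig <- igraph::degree(g)
  d <- degrees(r$net)
  expect_equal(unname(d_ig[names(d)]), unname(as.numeric(d)))
  tmp <- tempfile(fileext = ".graphml")
  writeGraphML(r$net, tmp)
  expect_true(file.size(tmp) > 0)
  edge_tsv <- tempfile(); node_tsv <- tempfile()
  writeEdgeList(r$net, edge_tsv); writeNodeTable(r$net, node_tsv)
  edges <- read.delim(edge_tsv)
  expect_equal(nrow(edges), nrow(r$net@edges))
  expect_true(all(edges$source_type == "mirna"))
  nodes <- read.delim(node_tsv)
  expect_setequal(nodes$id, c(r$net@leftNodes$id, r$net@rightNodes$id))
})
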