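test_that("loadEdgeTable returns raw pairs verbatim, with errors on bad rows", {
  tf <- withr::local_tempfile()
  writeLines(c("# comment", "A\tB", "B\tA", "A\tA"), tf)
  suppressMessages(tb <- loadEdgeTable(tf))
  expect_equal(tb$from, c("A", "B", "A"))
  expect_equal(tb$to, c("B", "A", "A"))

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  suppressMessages(expect_equal(nrow(loadEdgeTable(empty)), 0L))

  expect_error(loadEdgeTable(file.path(tempdir(), "nope.tsv")), "not found")
  bad <- withr::local_tempfile()
  writeLines(c("A\tB", "C"), bad)
  suppressMessages(expect_error(loadEdgeTable(bad), "row 2"))
})

test_that("buildPIN removes self-loops, collapses direction, merges duplicates", {
  t1 <- data.frame(from = c("A", "B"), to = c("B", "C"))
  t2 <- data.frame(from = c("B", "A"), to = c("A", "A"))
  net <- buildPIN(list(s1 = t1, s2 = t2))
  expect_setequal(geneIds(net), c("A", "B", "C"))
  expect_equal(numEdges(net), 2L)
  # empty input yields an empty network
  expect_equal(length(geneIds(buildPIN(list()))), 0L)
  expect_equal(numEdges(buildPIN(list())), 0L)
})

test_that("buildPIN is idempotent and order-invariant", {
  set.seed(11)
  pairs <- data.frame(from = sample(LETTERS[1:8], 40, TRUE),
                      to = sample(LETTERS[1:8], 40, TRUE))
  net1 <- buildPIN(list(pairs))
  # rebuild from its own canonical edge output
  tf <- withr::local_tempfile()
  writePIN(net1, tf)
  net2 <- readPIN(tf)
  expect_setequal(geneIds(net1), geneIds(net2))
  expect_equal(numEdges(net1), numEdges(net2))
  # permuted rows and table order
  perm <- pairs[sample(nrow(pairs)), ]
  net3 <- buildPIN(list(perm[1:13, ], perm[14:40, ]))
  tf3 <- withr::local_tempfile()
  writePIN(net3, tf3)
  expect_identical(readLines(tf), readLines(tf3))
})

test_that("network density follows 2E/(N(N-1)) with the N<=1 convention", {
  tri <- pinFromEdges(c("A-B", "B-C", "C-A"))
  expect_equal(networkDensity(tri), 1)
  lone <- asPINetwork(data.frame(from = character(), to = character()),
                      vertices = "A")
  expect_equal(networkDensity(lone), 0)
  expect_equal(edgeDensityFromCounts(10, 45), 1)
  # monotone in added edges at fixed node set
  d <- vapply(1:6, function(e) edgeDensityFromCounts(6, e), 0)
  expect_true(all(diff(d) > 0))
})

test_that("centralities match hand-derived and brute-force values", {
  star <- pinFromEdges(c("h-a", "h-b", "h-c"))
  cc <- computeCentralities(star)
  expect_equal(cc$degree[cc$gene == "h"], 1)
  expect_equal(cc$degree[cc$gene != "h"], rep(1 / 3, 3))

  path <- pinFromEdges(c("A-B", "B-C"))
  cp <- computeCentralities(path)
  expect_equal(cp$betweenness[cp$gene == "B"], 1)
  expect_equal(cp$betweenness[cp$gene != "B"], c(0, 0))

  tri <- pinFromEdges(c("A-B", "B-C", "C-A"))
  ct <- computeCentralities(tri)
  expect_equal(ct$eigenvector, rep(ct$eigenvector[1], 3), tolerance = 1e-8)
  # vertex-transitive: all four metrics constant across nodes
  for (m in c("degree", "betweenness", "closeness", "eigenvector"))
    expect_equal(diff(range(ct[[m]])), 0, tolerance = 1e-8)
  # degree centralities sum to 2E/(N-1)
  set.seed(5)
  g <- erPIN(30, 0.15)
  cg <- computeCentralities(g)
  expect_equal(sum(cg$degree), 2 * numEdges(g) / (length(geneIds(g)) - 1))
})

test_that("closeness and eigenvector agree with igraph on a connected graph", {
  set.seed(9)
  net <- erPIN(40, 0.15)
  stopifnot(igraph::is_connected(net@graph))
  cc <- computeCentralities(net)
  ig_clo <- igraph::closeness(net@graph, normalized = TRUE)
  expect_equal(cc$closeness, unname(ig_clo[cc$gene]), tolerance = 1e-10)
  ig_eig <- igraph::eigen_centrality(net@graph)$vector
  ig_eig <- ig_eig / sqrt(sum(ig_eig^2))
  expect_equal(cc$eigenvector, unname(ig_eig[cc$gene]), tolerance = 1e-6)
})

test_that("disconnected graphs get reachable-set closeness, zero for isolates", {
  net <- asPINetwork(data.frame(from = c("A", "C"), to = c("B", "D")),
                     vertices = c("A", "B", "C", "D", "E"))
  cc <- computeCentralities(net)
  # each pair member reaches 1 node at distance 1: (1/4) * (1/1)
  expect_equal(cc$closeness[cc$gene == "A"], 0.25)
  expect_equal(cc$closeness[cc$gene == "E"], 0)
})

test_that("subnetworkMetrics matches the exhaustive BFS oracle", {
  tri <- pinFromEdges(c("A-B", "B-C", "C-A"))
  m <- subnetworkMetrics(tri, c("A", "B", "C"))
  expect_equal(m, list(lcc_size = 3L, n_edges = 3L, density = 1,
                       avg_shortest_path = 1))
  iso <- asPINetwork(data.frame(from = character(), to = character()),
                     vertices = c("A", "B", "C"))
  m2 <- subnetworkMetrics(iso, c("A", "B", "C"))
  expect_equal(m2$lcc_size, 1L)
  expect_equal(m2$n_edges, 0L)
  expect_equal(m2$density, 0)
  expect_true(is.na(m2$avg_shortest_path))

  set.seed(21)
  for (rep in 1:5) {
    nm <- sprintf("g%02d", 1:25)
    pairs <- utils::combn(nm, 2)
    keep <- stats::runif(ncol(pairs)) < 0.12
    edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep])
    net <- asPINetwork(edges, vertices = nm)
    genes <- sample(nm, 15)
    got <- subnetworkMetrics(net, genes)
    want <- subnetMetricsOracle(edges, sort(genes))
    expect_equal(got$lcc_size, want$lcc_size)
    expect_equal(got$n_edges, want$n_edges)
    expect_equal(got$density, want$density)
    expect_equal(got$avg_shortest_path, unname(want$avg_shortest_path))
  }
  # full node set reproduces the whole-network density
  set.seed(3)
  net <- erPIN(20, 0.2)
  expect_equal(subnetworkMetrics(net, geneIds(net))$density,
               networkDensity(net))
  expect_warning(subnetworkMetrics(net, c(geneIds(net)[1], "ZZZ")), "dropped")
})

test_that("rocAUC equals exhaustive pair counting and obeys the flip identity", {
  expect_equal(rocAUC(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAUC(rep(2, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  expect_error(rocAUC(1:4, rep(TRUE, 4)), "both")
  set.seed(14)
  for (rep in 1:4) {
    score <- sample(1:10, 50, TRUE)  # plenty of ties
    outcome <- stats::runif(50) < 0.4
    if (length(unique(outcome)) < 2) next
    expect_equal(rocAUC(score, outcome), aucOracle(score, outcome))
    expect_equal(rocAUC(score, outcome) + rocAUC(-score, outcome), 1)
    # independent ROC implementation agrees
    ref <- as.numeric(pROC::auc(pROC::roc(outcome, score,
                                          direction = "<", quiet = TRUE)))
    expect_equal(rocAUC(score, outcome), ref, tolerance = 1e-12)
  }
})
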