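test_that("hypergeometric tail matches exhaustive enumeration and is monotone", {
  expect_equal(hypergeomTailP(0, 5, 4, 10), 1)
  expect_equal(hypergeomTailP(5, 5, 10, 10), 1)  # certain event
  expect_error(hypergeomTailP(6, 5, 4, 10), "inconsistent")
  cases <- list(c(3, 5, 4, 10), c(2, 6, 7, 12), c(1, 4, 3, 15), c(4, 7, 9, 14))
  for (cs in cases) {
    expect_equal(hypergeomTailP(cs[1], cs[2], cs[3], cs[4]),
                 hyperTailOracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  p <- vapply(0:5, function(M) hypergeomTailP(M, 5, 6, 12), 0)
  expect_true(all(diff(p) <= 0))
})

test_that("fold enrichment is the ratio of fractions", {
  expect_equal(foldEnrichment(4, 10, 20, 100), 2)
  expect_equal(foldEnrichment(2, 10, 20, 100), 1)
  expect_equal(foldEnrichment(0, 10, 20, 100), 0)
  expect_error(foldEnrichment(0, 0, 5, 10), "positive")
})

test_that("sampling-enrichment null matches hypergeometric moments", {
  set.seed(101)
  pool <- sprintf("g%03d", 1:60)
  annotation <- list(pw1 = pool[1:12], pw2 = pool[10:30], all = pool)
  positives <- sample(pool, 15)
  e <- pathwaySamplingZ(positives, pool, annotation, nSamples = 10000)
  for (pw in c("pw1", "pw2")) {
    K <- e$K[e$pathway == pw]
    hmean <- 15 * K / 60
    hvar <- 15 * (K / 60) * (1 - K / 60) * (60 - 15) / 59
    se <- sqrt(hvar / 10000)
    expect_lt(abs(e$expected[e$pathway == pw] - hmean), 4 * se)
    expect_lt(abs(e$null_sd[e$pathway == pw] - sqrt(hvar)), 0.1)
  }
  # pathway equal to the whole pool: zero-variance null, flagged undefined
  expect_true(is.na(e$z[e$pathway == "all"]))
  # concentrated positives give a large positive z
  e2 <- pathwaySamplingZ(pool[1:10], pool,
                         list(pw = pool[1:10], other = pool[40:60]),
                         nSamples = 2000)
  expect_gt(e2$z[e2$pathway == "pw"], 3)
  expect_error(pathwaySamplingZ(c("nope"), pool, annotation), "pool")
})

test_that("degree bins accumulate from low degree and merge the tail backwards", {
  set.seed(33)
  net <- erPIN(60, 0.1)
  bins <- makeDegreeBins(net, minSize = 10)
  deg <- igraph::degree(net@graph)
  # bins partition the node set
  expect_setequal(unlist(bins$bins), geneIds(net))
  expect_equal(sum(lengths(bins$bins)), length(geneIds(net)))
  # every bin meets the minimum size and ranges are ascending/disjoint
  expect_true(all(lengths(bins$bins) >= 10))
  expect_true(all(diff(as.vector(t(bins$ranges))) >= 0))
  # a node's bin covers its degree
  for (i in seq_along(bins$bins))
    expect_true(all(deg[bins$bins[[i]]] >= bins$ranges[i, 1] &
                    deg[bins$bins[[i]]] <= bins$ranges[i, 2]))
  # min_size >= N: a single bin with everything
  b1 <- makeDegreeBins(net, minSize = 1000)
  expect_equal(length(b1$bins), 1L)
  expect_setequal(b1$bins[[1]], geneIds(net))
  # regular graph: a single degree value, a single bin
  ring <- asPINetwork(igraph::make_ring(12))
  expect_equal(length(makeDegreeBins(ring, minSize = 3)$bins), 1L)
})

test_that("degree bins close exactly at the documented accumulation points", {
  # degrees: 4 nodes of degree 1, 3 of degree 2, 3 of degree 3; min size 3
  g <- igraph::graph_from_literal(p1 - q1, p2 - q2, c1 - c2, c2 - c3, c3 - c1)
  g <- igraph::add_vertices(g, 0)
  net <- asPINetwork(g)
  deg <- igraph::degree(net@graph)
  bins <- makeDegreeBins(net, minSize = 3)
  degSets <- lapply(bins$bins, function(b) sort(unname(unique(deg[b]))))
  expect_equal(degSets, list(1, 2))  # one bin closes per degree value
})

test_that("degree-matched samples reproduce the target bin counts exactly", {
  set.seed(55)
  net <- erPIN(80, 0.08)
  bins <- makeDegreeBins(net, minSize = 15)
  target <- sample(geneIds(net), 20)
  targetCounts <- vapply(bins$bins, function(b) sum(target %in% b), 1L)
  for (i in 1:200) {
    s <- degreeMatchedSample(net, target, bins)
    expect_equal(length(s), 20L)
    expect_equal(vapply(bins$bins, function(b) sum(s %in% b), 1L),
                 targetCounts)
  }
  expect_equal(degreeMatchedSample(net, character(), bins), character())
  # exclusion switch keeps target genes out
  s <- degreeMatchedSample(net, target, bins, excludeTarget = TRUE)
  expect_equal(length(intersect(s, target)), 0L)
})

test_that("metric nulls recover closed-form expectations and degenerate cases", {
  set.seed(77)
  p <- 0.1
  net <- erPIN(120, p)
  pool <- geneIds(net)
  # sampling the full node set: zero-variance null at the whole-network value
  nulls <- metricNullDistribution(net, pool, pool = pool, nSamples = 5)
  expect_equal(nullSd(nulls$density), 0)
  expect_equal(nullMean(nulls$density), networkDensity(net))
  # edge-count null mean ~ k(k-1)p/2 on an Erdos-Renyi graph
  k <- 20
  nulls <- metricNullDistribution(net, pool[1:k], pool = pool, nSamples = 200)
  expected <- k * (k - 1) / 2 * networkDensity(net)
  se <- nullSd(nulls$n_edges) / sqrt(200)
  expect_lt(abs(nullMean(nulls$n_edges) - expected), 6 * se)
  # n = 1 sample: mean equals the single draw, sd undefined
  n1 <- metricNullDistribution(net, pool[1:5], pool = pool, nSamples = 1)
  expect_equal(length(nullSamples(n1$n_edges)), 1L)
  expect_true(is.na(nullSd(n1$n_edges)))
})

test_that("stochastic samplers are reproducible under a fixed seed", {
  set.seed(1); net1 <- erPIN(50, 0.1)
  set.seed(1); net2 <- erPIN(50, 0.1)
  expect_equal(igraph::as_edgelist(net1@graph), igraph::as_edgelist(net2@graph))
  bins <- makeDegreeBins(net1, minSize = 10)
  target <- geneIds(net1)[1:10]
  set.seed(2); s1 <- degreeMatchedSample(net1, target, bins)
  set.seed(2); s2 <- degreeMatchedSample(net1, target, bins)
  expect_identical(s1, s2)
})

test_that("modularity z detects a planted dense module", {
  set.seed(202)
  cfg <- synthConfig(nGenes = 120, moduleSizes = 20L, withinDensity = 0.5,
                     backgroundDensity = 0.02, nExtraNodes = 30,
                     nPathways = 3, pathwaySizeRange = c(10, 25))
  pin <- simulatePIN(cfg)
  module <- pin$truth$gene[!is.na(pin$truth$module)]
  obs <- subnetworkMetrics(pin$net, module)
  nulls <- metricNullDistribution(pin$net, module, nSamples = 300)
  mz <- modularityZ(obs, nulls)
  expect_gt(mz$z[mz$metric == "lcc_size"], 3)
  expect_gt(mz$z[mz$metric == "density"], 3)
  expect_true(mz$modular[mz$metric == "lcc_size"])
  # observed equal to the null mean gives z = 0; below gives negative z
  fake <- nulls
  obs0 <- list(lcc_size = nullMean(nulls$lcc_size),
               n_edges = nullMean(nulls$n_edges) - 5,
               density = nullMean(nulls$density),
               avg_shortest_path = nullMean(nulls$avg_shortest_path))
  mz0 <- modularityZ(obs0, fake)
  expect_equal(mz0$z[mz0$metric == "lcc_size"], 0)
  expect_lt(mz0$z[mz0$metric == "n_edges"], 0)
})
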