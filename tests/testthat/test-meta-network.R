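# assemble a minimal SCAResult directly for grouping tests
mkRes <- function(seeds, conns) {
  tr <- data.frame(iteration = 0L, gene = NA_character_,
                   coverage = length(seeds), lcc_size = length(seeds),
                   stringsAsFactors = FALSE)
  methods::new("SCAResult", seedsRetained = seeds,
               seedsDropped = character(), connectors = conns,
               trace = tr, finalLCC = c(seeds, conns))
}

test_that("meta groups follow the Venn-region mapping", {
  calls <- rbind(
    data.frame(screen = "hpo_egg_laying", gene = c("core1", "he1", "slp"),
               call = c("negative", "negative", "none")),
    data.frame(screen = "egg_laying", gene = c("core1", "el1", "slp"),
               call = c("negative", "positive", "positive")),
    data.frame(screen = "hpo_ovariole", gene = c("core1", "ov1"),
               call = c("negative", "positive"))
  )
  sca <- list(
    core = mkRes("core1", "cc1"),
    hpo_egg_laying = mkRes(c("core1", "he1"), c("hec1", "slp")),
    egg_laying = mkRes(c("core1", "el1", "slp"), character()),
    hpo_ovariole = mkRes(c("core1", "ov1"), c("ovc1"))
  )
  g <- assignMetaGroups(sca, calls)
  grp <- stats::setNames(g$group, g$gene)
  expect_equal(unname(grp["core1"]), "IV")     # positive in all three
  expect_equal(unname(grp["cc1"]), "IV")       # core connector
  expect_equal(unname(grp["he1"]), "I")
  expect_equal(unname(grp["el1"]), "II")
  expect_equal(unname(grp["ov1"]), "III")
  expect_equal(unname(grp["hec1"]), "I")       # connector of one network
  expect_equal(unname(grp["ovc1"]), "III")
  # seed in egg_laying + connector in hpo_egg_laying: combined signature
  expect_equal(unname(grp["slp"]), "VII")
  expect_equal(g$role[g$gene == "slp"], "seed")
  # every meta gene lands in exactly one group
  expect_equal(anyDuplicated(g$gene), 0L)
  # seed-only analysis keeps the same groups for seeds
  gs <- assignMetaGroups(sca, calls, includeConnectors = FALSE)
  seedsOnly <- g[g$role == "seed", c("gene", "group")]
  expect_equal(gs[order(gs$gene), c("gene", "group")],
               seedsOnly[order(seedsOnly$gene), c("gene", "group")],
               ignore_attr = TRUE)
})

test_that("pairwise edge densities match a brute-force edge scan", {
  net <- pinFromEdges(c("A-C", "A-D", "B-E", "A-B", "D-E"))
  groups <- data.frame(gene = c("A", "B", "C", "D", "E"),
                       group = c("g1", "g1", "g2", "g2", "g2"))
  d <- pairwiseEdgeDensity(net, groups)
  cross <- d[d$group_a == "g1" & d$group_b == "g2", ]
  expect_equal(cross$edges, 3L)  # A-C, A-D, B-E
  expect_equal(cross$density, 3 / 6)
  diag1 <- d[d$group_a == "g1" & d$group_b == "g1", ]
  expect_equal(diag1$edges, 1L)  # A-B
  expect_equal(diag1$density, 1)
  diag2 <- d[d$group_a == "g2" & d$group_b == "g2", ]
  expect_equal(diag2$edges, 1L)  # D-E
  expect_equal(diag2$density, 1 / 3)
  # no internal edges -> diagonal density 0 (defined, not NA)
  g2 <- data.frame(gene = c("C", "D"), group = "x")
  netCD <- pinFromEdges(c("A-C", "A-D"))
  d2 <- pairwiseEdgeDensity(netCD, g2)
  expect_equal(d2$density[d2$group_a == "x"], 0)

  # random partitions equal an exhaustive edge classification
  set.seed(91)
  for (rep in 1:4) {
    net <- erPIN(30, 0.12)
    groups <- data.frame(gene = geneIds(net),
                         group = sample(c("u", "v", "w"), 30, TRUE))
    d <- pairwiseEdgeDensity(net, groups)
    el <- igraph::as_edgelist(net@graph)
    lab <- stats::setNames(groups$group, groups$gene)
    for (r in seq_len(nrow(d))) {
      a <- d$group_a[r]; b <- d$group_b[r]
      cnt <- sum((lab[el[, 1]] == a & lab[el[, 2]] == b) |
                 (lab[el[, 1]] == b & lab[el[, 2]] == a))
      if (a == b) cnt <- sum(lab[el[, 1]] == a & lab[el[, 2]] == a)
      expect_equal(d$edges[r], cnt)
    }
    # totals: all classified edges sum to the edges internal to the union
    expect_equal(sum(d$edges), nrow(el))
    # symmetry is implicit: each unordered pair appears once
    expect_equal(anyDuplicated(paste(d$group_a, d$group_b)), 0L)
  }
})

test_that("size-1 and empty diagonals propagate as undefined, not zero", {
  net <- pinFromEdges(c("A-B"))
  d <- pairwiseEdgeDensity(net, data.frame(gene = c("A", "B"),
                                           group = c("solo", "duo")))
  expect_true(is.na(d$density[d$group_a == "solo" & d$group_b == "solo"]))
})

test_that("permutation z flags planted assortative structure", {
  set.seed(120)
  cfg <- synthConfig(nGenes = 60, moduleSizes = c(12L, 12L),
                     withinDensity = 0.5, backgroundDensity = 0.02,
                     nExtraNodes = 10, nPathways = 3,
                     pathwaySizeRange = c(8, 15))
  pin <- simulatePIN(cfg)
  truth <- pin$truth
  mod <- truth$gene[!is.na(truth$module)]
  other <- setdiff(geneIds(pin$net), mod)
  groups <- data.frame(
    gene = c(mod, other[1:20]),
    group = c(paste0("m", truth$module[match(mod, truth$gene)]),
              rep("bg", 20)))
  z <- groupPermutationZ(pin$net, groups, nPermutations = 300)
  diag1 <- z[z$group_a == "m1" & z$group_b == "m1", ]
  diag2 <- z[z$group_a == "m2" & z$group_b == "m2", ]
  expect_gt(diag1$z, 3)
  expect_gt(diag2$z, 3)
  cross <- z[z$group_a == "m1" & z$group_b == "m2", ]
  expect_lt(cross$z, -1.5)  # modules are otherwise-separate by construction
  # single group: permutation cannot move anything, sd = 0, undefined
  one <- data.frame(gene = mod, group = "all")
  expect_error(groupPermutationZ(pin$net, one), "two groups")
})

test_that("self-generated labels give near-null permutation z values", {
  set.seed(131)
  net <- erPIN(40, 0.15)
  zs <- replicate(20, {
    groups <- data.frame(gene = geneIds(net),
                         group = sample(rep(c("a", "b"), each = 20)))
    z <- groupPermutationZ(net, groups, nPermutations = 100)
    z$z[z$group_a == "a" & z$group_b == "a"]
  })
  expect_lt(abs(mean(zs)), 0.5)
  expect_lt(max(abs(zs)), 4)
})

test_that("pathway proportions equal a direct recount and allow multi-membership", {
  groups <- data.frame(gene = c("a", "b", "c", "d"), group = "G")
  ann <- list(Notch = c("a", "b"), Wnt = c("a", "b", "c", "d"))
  p <- pathwayProportions(groups, ann)
  expect_equal(p$fraction[p$pathway == "Notch"], 0.5)
  expect_equal(p$fraction[p$pathway == "Wnt"], 1)
  expect_gt(sum(p$fraction), 1)  # multi-membership can exceed 1
  none <- pathwayProportions(groups, list(Hh = c("x", "y")))
  expect_equal(none$fraction, 0)
  expect_error(pathwayProportions(groups[0, ], ann), "empty")
  set.seed(8)
  genes <- sprintf("g%02d", 1:30)
  groups <- data.frame(gene = genes, group = sample(c("A", "B"), 30, TRUE))
  ann <- list(p1 = sample(genes, 10), p2 = sample(genes, 15))
  p <- pathwayProportions(groups, ann)
  for (r in seq_len(nrow(p))) {
    mem <- groups$gene[groups$group == p$group[r]]
    expect_equal(p$fraction[r], length(intersect(mem, ann[[p$pathway[r]]])) /
                   length(mem))
  }
})
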