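# Shared oracles and graph builders, independent of the package's own
# graph machinery wherever a test compares against them.

# build a PINetwork from an edge matrix/vector notation "A-B"
pinFromEdges <- function(edges, vertices = NULL) {
  parts <- strsplit(edges, "-", fixed = TRUE)
  asPINetwork(data.frame(from = vapply(parts, `[[`, "", 1),
                         to = vapply(parts, `[[`, "", 2)),
              vertices = vertices)
}

# adjacency list from an edge data.frame (plain R, no igraph)
adjList <- function(edges, vertices) {
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# BFS distances from one source over an adjacency list; Inf if unreachable
bfsDist <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      nxt <- c(nxt, w)
    }
    frontier <- nxt
  }
  d
}

# connected components via repeated BFS (plain R oracle)
componentsOracle <- function(adj) {
  left <- names(adj)
  comps <- list()
  while (length(left)) {
    d <- bfsDist(adj[left], left[1])
    comp <- names(d)[is.finite(d)]
    comps[[length(comps) + 1L]] <- comp
    left <- setdiff(left, comp)
  }
  comps
}

# sub-network metrics recomputed by exhaustive pairwise BFS
subnetMetricsOracle <- function(edges, genes) {
  keep <- edges$from %in% genes & edges$to %in% genes
  e <- edges[keep, , drop = FALSE]
  adj <- adjList(e, genes)
  comps <- componentsOracle(adj)
  sizes <- vapply(comps, length, 1L)
  big <- comps[sizes == max(sizes)]
  lcc <- big[[order(vapply(big, min, ""))[1]]]
  n <- length(genes)
  dens <- if (n <= 1) 0 else nrow(e) / (n * (n - 1) / 2)
  asp <- NA_real_
  if (length(lcc) >= 2) {
    adjL <- adjList(e[e$from %in% lcc & e$to %in% lcc, , drop = FALSE], lcc)
    tot <- 0; np <- 0
    for (i in seq_along(lcc)) {
      d <- bfsDist(adjL, lcc[i])
      for (j in seq_along(lcc)) if (j > i) { tot <- tot + d[lcc[j]]; np <- np + 1 }
    }
    asp <- tot / np
  }
  list(lcc_size = length(lcc), n_edges = nrow(e), density = dens,
       avg_shortest_path = asp)
}

# AUC by exhaustive positive x negative pair counting
aucOracle <- function(score, outcome) {
  pos <- score[as.logical(outcome)]
  neg <- score[!as.logical(outcome)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
hyperTailOracle <- function(M, n, K, N_pool) {
  draws <- utils::combn(N_pool, n)
  inK <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% inK))
  mean(hits >= M)
}

# a small Erdos-Renyi PINetwork with deterministic naming
erPIN <- function(n, p, prefix = "v") {
  nm <- sprintf("%s%03d", prefix, seq_len(n))
  pairs <- utils::combn(nm, 2)
  keep <- stats::runif(ncol(pairs)) < p
  asPINetwork(data.frame(from = pairs[1, keep], to = pairs[2, keep]),
              vertices = nm)
}

# small synthetic config used across tests (kept light for speed)
testSynthConfig <- function(...) {
  args <- list(nGenes = 120L, genesPerBatch = 40L,
               moduleSizes = c(8L, 7L, 6L), nExtraNodes = 25L,
               nPathways = 5L, pathwaySizeRange = c(8L, 20L))
  override <- list(...)
  args[names(override)] <- override
  do.call(synthConfig, args)
}

# exhaustive-search oracles for the Seed Connector Algorithm
# best coverage achievable by adding any single non-member node
bestSingleAddition <- function(net, members, seeds) {
  cand <- setdiff(geneIds(net), members)
  best <- scaCoverage(net, members, seeds)$coverage
  for (v in cand)
    best <- max(best, scaCoverage(net, c(members, v), seeds)$coverage)
  best
}

# best coverage achievable by any ordered sequence of <= k additions
bestKAdditions <- function(net, members, seeds, k) {
  if (k == 0) return(scaCoverage(net, members, seeds)$coverage)
  cand <- setdiff(geneIds(net), members)
  best <- scaCoverage(net, members, seeds)$coverage
  for (v in cand)
    best <- max(best, bestKAdditions(net, c(members, v), seeds, k - 1))
  best
}

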