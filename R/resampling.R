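#' Hypergeometric over-representation tail probability
#'
#' Probability of observing at least \code{M} members of a pathway of size
#' \code{K} (within a reference pool of \code{N_pool} genes) in a drawn set
#' of \code{n} genes: \eqn{P(X \ge M)} for \eqn{X \sim}
#' Hypergeometric(\code{N_pool}, \code{K}, \code{n}). The tail is
#' inclusive, the standard over-representation convention.
#'
#' @param M observed overlap count
#' @param n size of the drawn gene set
#' @param K pathway size within the pool
#' @param N_pool reference pool size
#' @return probability in (0, 1]
#' @examples
#' hypergeomTailP(0, 5, 4, 10)  # 1
#' hypergeomTailP(3, 5, 4, 10)
#' @export
hypergeomTailP <- function(M, n, K, N_pool) {
  if (M < 0 || M > n || n > N_pool || K > N_pool || K < 0)
    stop("inconsistent hypergeometric counts")
  stats::phyper(M - 1, K, N_pool - K, n, lower.tail = FALSE)
}

#' Fold enrichment of a pathway in a gene set
#'
#' Ratio of the observed pathway fraction in the drawn set to its fraction
#' in the pool: \eqn{(M/n) / (K/N_{pool})}.
#'
#' @inheritParams hypergeomTailP
#' @return fold enrichment (1 means exactly as expected)
#' @examples
#' foldEnrichment(4, 10, 20, 100)  # 2
#' @export
foldEnrichment <- function(M, n, K, N_pool) {
  if (n <= 0 || K <= 0) stop("n and K must be positive")
  (M / n) / (K / N_pool)
}

#' Monte-Carlo pathway enrichment Z scores
#'
#' For each pathway, compares the observed number of positive candidates
#' belonging to it against a null distribution built by drawing
#' \code{length(positives)} genes uniformly without replacement from the
#' reference pool, \code{nSamples} times. The Z score is (observed - null
#' mean)/null sd; hypergeometric tail p-values and fold enrichments are
#' reported alongside, plus a Benjamini-Hochberg adjusted column for
#' transparency (no correction is applied to the primary p).
#'
#' @param positives character vector of positive-candidate genes (must be a
#'   subset of \code{pool})
#' @param pool character vector: the reference gene universe (e.g. the 463
#'   screened signalling genes)
#' @param annotation named list mapping pathway name to character vector of
#'   member genes (multi-membership across pathways allowed)
#' @param nSamples number of null draws (default 10000, minimum 100)
#' @return data.frame with one row per pathway: \code{pathway}, \code{K}
#'   (pathway size in pool), \code{observed}, \code{expected} (null mean),
#'   \code{null_sd}, \code{z} (\code{NA} when the null sd is zero),
#'   \code{fold}, \code{p} (hypergeometric tail), \code{p_bh}
#' @export
pathwaySamplingZ <- function(positives, pool, annotation, nSamples = 10000L) {
  positives <- unique(as.character(positives))
  pool <- unique(as.character(pool))
  if (!all(positives %in% pool))
    stop("all positive genes must belong to the reference pool")
  if (nSamples < 100L) stop("at least 100 null samples are required")
  nPos <- length(positives)
  members <- lapply(annotation, function(g) intersect(unique(g), pool))
  K <- vapply(members, length, 1L)
  observed <- vapply(members, function(g) length(intersect(g, positives)), 1L)
  inPath <- vapply(members, function(g) pool %in% g,
                   logical(length(pool)))  # |pool| x nPathway
  nullM <- matrix(0L, nSamples, length(annotation))
  for (s in seq_len(nSamples)) {
    idx <- sample.int(length(pool), nPos)
    nullM[s, ] <- colSums(inPath[idx, , drop = FALSE])
  }
  nullMean <- colMeans(nullM)
  nullSd <- apply(nullM, 2, stats::sd)
  z <- ifelse(nullSd > 0, (observed - nullMean) / nullSd, NA_real_)
  p <- mapply(hypergeomTailP, observed, nPos, K, length(pool))
  fold <- ifelse(K > 0 & nPos > 0, (observed / nPos) / (K / length(pool)),
                 NA_real_)
  data.frame(pathway = names(annotation), K = K, observed = observed,
             expected = nullMean, null_sd = nullSd, z = z, fold = fold,
             p = p, p_bh = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin network nodes by degree
#'
#' Builds ascending degree bins for degree-controlled sampling: nodes are
#' accumulated from the lowest to the highest degree value, and a bin is
#' closed once it holds at least \code{minSize} nodes. A trailing bin
#' smaller than \code{minSize} is merged backwards into the previous bin,
#' so the bins always partition the node set and (when more than one bin
#' exists) each holds at least \code{minSize} nodes.
#'
#' @param net a non-empty \linkS4class{PINetwork}
#' @param minSize minimum bin occupancy (default 100, as used for
#'   interactome-scale networks)
#' @return object of class \code{DegreeBins}: list with \code{bins} (list
#'   of character vectors of gene ids), \code{ranges} (2-column matrix of
#'   inclusive degree bounds) and \code{degree} (named degree vector)
#' @export
makeDegreeBins <- function(net, minSize = 100L) {
  g <- net@graph
  if (igraph::vcount(g) == 0) stop("network is empty")
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  vals <- sort(unique(deg))
  bins <- list(); ranges <- NULL
  cur <- character(); lo <- vals[1]
  for (d in vals) {
    cur <- c(cur, names(deg)[deg == d])
    if (length(cur) >= minSize) {
      bins[[length(bins) + 1L]] <- cur
      ranges <- rbind(ranges, c(lo, d))
      cur <- character()
      nxt <- vals[vals > d]
      lo <- if (length(nxt)) nxt[1] else NA
    }
  }
  if (length(cur)) {
    if (length(bins)) {
      bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
      ranges[nrow(ranges), 2] <- vals[length(vals)]
    } else {
      bins[[1L]] <- cur
      ranges <- rbind(ranges, c(lo, vals[length(vals)]))
    }
  }
  structure(list(bins = bins, ranges = ranges, degree = deg),
            class = "DegreeBins")
}

#' Degree-matched random gene sample
#'
#' Draws a random gene set with the same per-degree-bin composition as a
#' target set: for each bin, as many genes are sampled uniformly without
#' replacement from the bin as the target has in it. The returned set
#' therefore reproduces the target's binned degree distribution exactly on
#' every draw. By default sampled genes may coincide with target genes;
#' set \code{excludeTarget} to sample from the bin complement instead.
#'
#' @param net a \linkS4class{PINetwork}
#' @param target character vector of target genes (subset of the network)
#' @param bins a \code{DegreeBins} object from \code{\link{makeDegreeBins}}
#' @param excludeTarget logical, forbid target genes in the sample
#' @return character vector of sampled genes, \code{length(target)} long
#' @export
degreeMatchedSample <- function(net, target, bins, excludeTarget = FALSE) {
  target <- unique(as.character(target))
  if (!all(target %in% geneIds(net)))
    stop("target genes must all be present in the network")
  out <- character()
  for (bin in bins$bins) {
    k <- sum(target %in% bin)
    if (k == 0L) next
    cand <- if (excludeTarget) setdiff(bin, target) else bin
    if (length(cand) < k)
      stop("bin too small to satisfy a degree-matched draw")
    out <- c(out, cand[sample.int(length(cand), k)])
  }
  out
}

#' Null distributions of sub-network metrics
#'
#' Repeatedly samples gene sets (uniformly from a pool, or degree-matched
#' to a target set) and evaluates \code{\link{subnetworkMetrics}} on each,
#' yielding one \linkS4class{NullDistribution} per metric. Samples on
#' which the average shortest path is undefined (LCC < 2) are excluded
#' from that metric's distribution, with the exclusion count recorded.
#'
#' @param net a \linkS4class{PINetwork}
#' @param target character vector: the observed gene set the null is
#'   matched to (its size sets the draw size)
#' @param sampler "uniform" (draw \code{length(target)} genes from
#'   \code{pool}) or "degree" (degree-matched draws via \code{bins})
#' @param pool character vector to sample from when \code{sampler =
#'   "uniform"}; defaults to all network genes
#' @param bins \code{DegreeBins}, required when \code{sampler = "degree"}
#' @param nSamples number of draws (default 1000)
#' @return named list of four \linkS4class{NullDistribution} objects:
#'   \code{lcc_size}, \code{n_edges}, \code{density},
#'   \code{avg_shortest_path}
#' @export
metricNullDistribution <- function(net, target,
                                   sampler = c("uniform", "degree"),
                                   pool = NULL, bins = NULL,
                                   nSamples = 1000L) {
  sampler <- match.arg(sampler)
  target <- unique(as.character(target))
  k <- length(target)
  if (sampler == "uniform") {
    if (is.null(pool)) pool <- geneIds(net)
    pool <- unique(as.character(pool))
    if (k > length(pool)) stop("pool smaller than the target set")
  } else if (is.null(bins)) {
    stop("degree-matched sampling requires 'bins'")
  }
  metrics <- c("lcc_size", "n_edges", "density", "avg_shortest_path")
  vals <- matrix(NA_real_, nSamples, 4, dimnames = list(NULL, metrics))
  for (s in seq_len(nSamples)) {
    genes <- if (sampler == "uniform") pool[sample.int(length(pool), k)]
             else degreeMatchedSample(net, target, bins)
    m <- suppressWarnings(subnetworkMetrics(net, genes))
    vals[s, ] <- c(m$lcc_size, m$n_edges, m$density, m$avg_shortest_path)
  }
  out <- lapply(metrics, function(mn) {
    v <- vals[, mn]
    excl <- sum(is.na(v))
    methods::new("NullDistribution", metric = mn, samples = v[!is.na(v)],
                 nExcluded = as.integer(excl))
  })
  names(out) <- metrics
  out
}

#' Modularity Z scores of an observed gene set against metric nulls
#'
#' For each metric, \eqn{z = (observed - null mean)/null sd}. The modular
#' verdict is reported as four booleans, not collapsed into one number: a
#' gene set shows modular features when its LCC, density and edge count
#' exceed the null and its average shortest path falls below it.
#'
#' @param observed list from \code{\link{subnetworkMetrics}}
#' @param nulls named list of \linkS4class{NullDistribution} objects from
#'   \code{\link{metricNullDistribution}}
#' @return data.frame with columns \code{metric}, \code{observed},
#'   \code{null_mean}, \code{null_sd}, \code{z} (NA where the null sd is
#'   zero or the observation undefined) and \code{modular} (the per-metric
#'   boolean verdict)
#' @export
modularityZ <- function(observed, nulls) {
  metrics <- names(nulls)
  obs <- vapply(metrics, function(mn) {
    v <- observed[[mn]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
  mu <- vapply(nulls, nullMean, 0)
  sdv <- vapply(nulls, nullSd, 0)
  z <- ifelse(!is.na(sdv) & sdv > 0, (obs - mu) / sdv, NA_real_)
  modular <- ifelse(metrics == "avg_shortest_path", obs < mu, obs > mu)
  data.frame(metric = metrics, observed = obs, null_mean = mu,
             null_sd = sdv, z = z, modular = modular,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn nullMean mean of the defined samples
#' @export
setMethod("nullMean", "NullDistribution", function(x) {
  if (!length(x@samples)) NA_real_ else mean(x@samples)
})

#' @describeIn nullSd sample standard deviation of the defined samples
#' @export
setMethod("nullSd", "NullDistribution", function(x) {
  if (length(x@samples) < 2L) NA_real_ else stats::sd(x@samples)
})

#' @describeIn nullSamples the defined samples
#' @export
setMethod("nullSamples", "NullDistribution", function(x) x@samples)
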