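#' @import methods
NULL

#' PINetwork: an undirected simple protein-interaction network
#'
#' Thin S4 container around an \pkg{igraph} graph holding the assembled
#' protein-interaction network (PIN) or any sub-network of it. The graph is
#' guaranteed simple (no self-loops, no duplicate edges) and undirected, with
#' gene identifiers as vertex names. Per-edge provenance (which source tables
#' contributed an interaction) is kept as an edge attribute when available.
#'
#' @slot graph an \code{igraph} object (undirected, simple, named vertices)
#'
#' @seealso \code{\link{buildPIN}}, \code{\link{networkDensity}},
#'   \code{\link{computeCentralities}}
#' @export
setClass("PINetwork", representation(graph = "ANY"))

setValidity("PINetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("'graph' must be an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    return("vertices must be named by gene identifier")
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  nm <- igraph::V(g)$name
  if (anyDuplicated(nm)) return("duplicate gene identifiers")
  if (length(nm) && any(!nzchar(nm) | grepl("[[:space:]]", nm)))
    return("gene identifiers must be non-empty and contain no whitespace")
  TRUE
})

#' SCAResult: output of the Seed Connector Algorithm
#'
#' Records which seed genes were retained (present in the PIN), which were
#' dropped, the connector genes in their order of addition, the coverage
#' trace (one row per accepted iteration, plus the initial state), and the
#' membership of the final largest connected component.
#'
#' @slot seedsRetained character, seed genes found in the network
#' @slot seedsDropped character, seed genes absent from the network
#' @slot connectors character, connector genes in order of addition
#' @slot trace data.frame with columns \code{iteration}, \code{gene},
#'   \code{coverage}, \code{lcc_size} (\code{gene} is \code{NA} for the
#'   initial state)
#' @slot finalLCC character, genes in the final largest connected component
#'
#' @seealso \code{\link{runSCA}}
#' @export
setClass("SCAResult", representation(
  seedsRetained = "character",
  seedsDropped  = "character",
  connectors    = "character",
  trace         = "data.frame",
  finalLCC      = "character"
))

setValidity("SCAResult", function(object) {
  if (length(intersect(object@connectors, object@seedsRetained)))
    return("connectors must be disjoint from retained seeds")
  cov <- object@trace$coverage
  if (length(cov) > 1 && any(diff(cov) <= 0))
    return("coverage must strictly increase along accepted iterations")
  if (length(cov) && max(cov) > length(object@seedsRetained))
    return("coverage cannot exceed the number of retained seeds")
  TRUE
})

#' NullDistribution: resampled values of a network metric
#'
#' Holds the raw resampled values of one metric under a network null model,
#' together with the number of samples on which the metric was undefined
#' (e.g. average shortest path when the sampled LCC has fewer than two
#' nodes); undefined samples are excluded from the stored values and from
#' the summary moments.
#'
#' @slot metric name of the metric ("lcc_size", "n_edges", "density" or
#'   "avg_shortest_path")
#' @slot samples numeric vector of defined resampled values
#' @slot nExcluded integer, count of samples excluded as undefined
#'
#' @seealso \code{\link{metricNullDistribution}}, \code{\link{modularityZ}}
#' @export
setClass("NullDistribution", representation(
  metric    = "character",
  samples   = "numeric",
  nExcluded = "integer"
))

setValidity("NullDistribution", function(object) {
  if (length(object@metric) != 1L) return("'metric' must be a single name")
  if (object@nExcluded < 0L) return("'nExcluded' must be non-negative")
  TRUE
})

setMethod("show", "PINetwork", function(object) {
  g <- object@graph
  cat("PINetwork with", igraph::vcount(g), "genes and",
      igraph::ecount(g), "interactions\n")
  cat("  density:", format(networkDensity(object), digits = 3), "\n")
  src <- igraph::edge_attr(g, "sources")
  if (!is.null(src))
    cat("  provenance recorded for", sum(nzchar(src)), "edges\n")
  invisible(object)
})

setMethod("show", "SCAResult", function(object) {
  cat("SCAResult:", length(object@seedsRetained), "seeds retained",
      sprintf("(%d dropped),", length(object@seedsDropped)),
      length(object@connectors), "connectors added\n")
  n <- nrow(object@trace)
  if (n) {
    cat("  final coverage:", object@trace$coverage[n],
        " final LCC size:", object@trace$lcc_size[n], "\n")
  }
  invisible(object)
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution of", object@metric, ":",
      length(object@samples), "samples")
  if (object@nExcluded > 0L) cat(" (", object@nExcluded, " undefined excluded)", sep = "")
  cat("\n  mean:", format(nullMean(object), digits = 4),
      " sd:", format(nullSd(object), digits = 4), "\n")
  invisible(object)
})
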