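#' Gene identifiers of a network
#'
#' @param x a \linkS4class{PINetwork}
#' @return character vector of gene identifiers (vertex names)
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Number of interactions in a network
#'
#' @param x a \linkS4class{PINetwork}
#' @return integer edge count
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Edge density of a network
#'
#' Density is \eqn{2E / (N(N-1))} for \eqn{N \ge 2} nodes and \eqn{E} edges;
#' by convention 0 for networks with at most one node.
#'
#' @param x a \linkS4class{PINetwork}
#' @return density in [0, 1]
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))

#' Connector genes of a Seed Connector Algorithm run
#'
#' @param x an \linkS4class{SCAResult}
#' @return character vector of connectors in order of addition
#' @export
setGeneric("connectors", function(x) standardGeneric("connectors"))

#' Retained seed genes of a Seed Connector Algorithm run
#'
#' @param x an \linkS4class{SCAResult}
#' @return character vector of seeds found in the network
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' Coverage trace of a Seed Connector Algorithm run
#'
#' @param x an \linkS4class{SCAResult}
#' @return data.frame with one row per accepted iteration (plus the initial
#'   state): iteration, gene added, seed coverage, LCC size
#' @export
setGeneric("coverageTrace", function(x) standardGeneric("coverageTrace"))

#' Mean of a resampled null distribution
#'
#' @param x a \linkS4class{NullDistribution}
#' @return mean of the defined samples (NA if none)
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))

#' Standard deviation of a resampled null distribution
#'
#' @param x a \linkS4class{NullDistribution}
#' @return sample standard deviation of the defined samples (NA if fewer
#'   than two)
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))

#' Raw samples of a resampled null distribution
#'
#' @param x a \linkS4class{NullDistribution}
#' @return numeric vector of defined samples
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))
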