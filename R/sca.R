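#' Largest connected component and seed coverage of a member set
#'
#' Computes the largest connected component (LCC) of the subgraph induced
#' by \code{members}, and the coverage: the number of seed genes contained
#' in that LCC. When two components tie in size, the one whose
#' lexicographically smallest member sorts first is taken, so the result
#' is deterministic.
#'
#' @param net a \linkS4class{PINetwork}
#' @param members character vector of current module members (subset of
#'   the network)
#' @param seeds character vector of seed genes (subset of \code{members})
#' @return list with \code{lcc} (character vector) and \code{coverage}
#'   (integer)
#' @examples
#' net <- asPINetwork(data.frame(from = c("A", "C"), to = c("B", "D")))
#' scaCoverage(net, c("A", "B", "C", "D"), c("A", "B", "C"))
#' @export
scaCoverage <- function(net, members, seeds) {
  members <- unique(as.character(members))
  if (!length(members)) return(list(lcc = character(), coverage = 0L))
  sub <- igraph::induced_subgraph(net@graph, members)
  lcc <- largestComponent(sub)
  list(lcc = lcc, coverage = length(intersect(lcc, seeds)))
}

#' Candidate connectors: the direct neighbourhood of the current LCC
#'
#' All network nodes adjacent (distance 1) to at least one node of the
#' current LCC and not already module members. Candidates are drawn from
#' the full network's adjacency to the LCC, not to all members.
#'
#' @param net a \linkS4class{PINetwork}
#' @param currentLcc character vector, the current LCC
#' @param members character vector of current module members
#' @return character vector of candidate genes (sorted)
#' @export
scaCandidates <- function(net, currentLcc, members) {
  if (!length(currentLcc)) return(character())
  idx <- unique(unlist(igraph::adjacent_vertices(net@graph, currentLcc)))
  nb <- igraph::V(net@graph)$name[idx]
  sort(setdiff(nb, members))
}

#' Run the Seed Connector Algorithm
#'
#' Greedy module growth: starting from the seed genes present in the
#' network, each iteration evaluates every gene in the direct
#' neighbourhood of the current largest connected component, recomputing
#' the LCC and seed coverage with that gene added. The candidate that
#' maximises coverage while minimising the LCC is accepted as a connector
#' (ties beyond that broken by smallest gene identifier); the loop stops
#' when no candidate strictly increases coverage. A candidate that leaves
#' coverage unchanged is never added, even if it merges components.
#'
#' Seeds absent from the network are dropped with a warning and recorded
#' in \code{seedsDropped}. Termination is guaranteed: coverage is an
#' integer, strictly increasing per accepted connector, and bounded by the
#' number of retained seeds.
#'
#' @param net a \linkS4class{PINetwork}
#' @param seeds character vector of seed genes
#' @return an \linkS4class{SCAResult}
#' @examples
#' path <- asPINetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' res <- runSCA(path, c("A", "C"))
#' connectors(res)  # "B"
#' @export
runSCA <- function(net, seeds) {
  seeds <- unique(as.character(seeds))
  nodes <- geneIds(net)
  retained <- intersect(seeds, nodes)
  dropped <- setdiff(seeds, nodes)
  if (length(dropped))
    warning(length(dropped), " seed gene(s) absent from the network were ",
            "dropped: ", paste(dropped, collapse = ", "))
  trace <- data.frame(iteration = integer(), gene = character(),
                      coverage = integer(), lcc_size = integer(),
                      stringsAsFactors = FALSE)
  if (!length(retained)) {
    return(methods::new("SCAResult", seedsRetained = character(),
                        seedsDropped = dropped, connectors = character(),
                        trace = trace, finalLCC = character()))
  }
  members <- retained
  state <- scaCoverage(net, members, retained)
  trace <- rbind(trace, data.frame(
    iteration = 0L, gene = NA_character_,
    coverage = state$coverage, lcc_size = length(state$lcc),
    stringsAsFactors = FALSE))
  connectors <- character()
  iter <- 0L
  repeat {
    cand <- scaCandidates(net, state$lcc, members)
    if (!length(cand)) break
    best <- NULL
    for (v in cand) {  # cand is sorted: first best seen wins ties
      st <- scaCoverage(net, c(members, v), retained)
      if (st$coverage <= state$coverage) next
      if (is.null(best) ||
          st$coverage > best$coverage ||
          (st$coverage == best$coverage &&
           length(st$lcc) < length(best$lcc))) {
        best <- st; best$gene <- v
      }
    }
    if (is.null(best)) break
    iter <- iter + 1L
    members <- c(members, best$gene)
    connectors <- c(connectors, best$gene)
    state <- list(lcc = best$lcc, coverage = best$coverage)
    trace <- rbind(trace, data.frame(
      iteration = iter, gene = best$gene,
      coverage = state$coverage, lcc_size = length(state$lcc),
      stringsAsFactors = FALSE))
  }
  methods::new("SCAResult", seedsRetained = retained,
               seedsDropped = dropped, connectors = connectors,
               trace = trace, finalLCC = state$lcc)
}

#' @describeIn connectors connectors of an SCAResult, in addition order
#' @export
setMethod("connectors", "SCAResult", function(x) x@connectors)

#' @describeIn seedGenes retained seeds of an SCAResult
#' @export
setMethod("seedGenes", "SCAResult", function(x) x@seedsRetained)

#' @describeIn coverageTrace coverage trace of an SCAResult
#' @export
setMethod("coverageTrace", "SCAResult", function(x) x@trace)

#' Final LCC membership of an SCA run
#'
#' @param x an \linkS4class{SCAResult}
#' @return character vector of genes in the final largest connected
#'   component
#' @export
finalLCC <- function(x) {
  stopifnot(methods::is(x, "SCAResult"))
  x@finalLCC
}

#' Module membership of an SCA run
#'
#' Seeds retained plus connectors: the gene content of the sub-network the
#' algorithm produced.
#'
#' @param x an \linkS4class{SCAResult}
#' @return character vector
#' @export
scaMembers <- function(x) {
  stopifnot(methods::is(x, "SCAResult"))
  c(x@seedsRetained, x@connectors)
}

#' Write an SCA result as a TSV table
#'
#' One row per module gene: role (seed/connector), addition order
#' (0 for seeds), and whether the gene sits in the final LCC.
#'
#' @param x an \linkS4class{SCAResult}
#' @param path output file path
#' @return invisibly, the path
#' @export
writeSCAResult <- function(x, path) {
  genes <- c(x@seedsRetained, x@connectors)
  role <- c(rep("seed", length(x@seedsRetained)),
            rep("connector", length(x@connectors)))
  ord <- c(rep(0L, length(x@seedsRetained)),
           seq_along(x@connectors))
  df <- data.frame(gene = genes, role = role, addition_order = ord,
                   in_final_lcc = genes %in% x@finalLCC)
  utils::write.table(df[order(df$role != "seed", df$addition_order, df$gene), ],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
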