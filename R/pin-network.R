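#' Read a two-column gene-pair edge table
#'
#' Parses one interaction source table (DroID-style export: tab-separated,
#' optionally with '#'-prefixed comment lines and a header to skip) and
#' returns the raw ordered gene pairs exactly as read, including duplicate
#' rows and self-pairs. Cleaning (deduplication, self-loop removal,
#' direction collapse) happens later in \code{\link{buildPIN}}, so that the
#' parsed row count can be compared against a source's documented size.
#'
#' @param path path to a tab-delimited file
#' @param columns integer pair: which columns hold the two gene identifiers
#' @param skip number of leading non-comment lines to skip (header lines)
#' @param comment.char comment prefix; such lines are ignored (default "#")
#' @param sep field separator (default tab)
#' @return data.frame with character columns \code{from} and \code{to}, one
#'   row per parsed data line; the number of parsed rows is reported via
#'   \code{message()}
#' @examples
#' tf <- tempfile()
#' writeLines(c("# src", "A\tB", "B\tA", "A\tA"), tf)
#' loadEdgeTable(tf)
#' @export
loadEdgeTable <- function(path, columns = c(1L, 2L), skip = 0L,
                          comment.char = "#", sep = "\t") {
  if (!file.exists(path)) stop("edge table not found: ", path)
  stopifnot(length(columns) == 2L)
  lines <- readLines(path)
  if (nzchar(comment.char))
    lines <- lines[!startsWith(trimws(lines), comment.char)]
  if (skip > 0L) lines <- lines[-seq_len(min(skip, length(lines)))]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    message("loadEdgeTable: 0 rows parsed from ", basename(path))
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < max(columns))
  if (length(short))
    stop("row ", short[1L], " of ", basename(path), " has fewer than ",
         max(columns), " columns")
  out <- data.frame(
    from = vapply(fields, `[[`, "", columns[1L]),
    to   = vapply(fields, `[[`, "", columns[2L]),
    stringsAsFactors = FALSE
  )
  message("loadEdgeTable: ", nrow(out), " rows parsed from ", basename(path))
  out
}

#' Assemble a protein-interaction network from edge tables
#'
#' Concatenates any number of gene-pair tables into a single undirected
#' simple network: self-pairs are removed, edge direction is collapsed
#' ((a,b) and (b,a) are the same edge), and duplicates are merged. The node
#' set is every endpoint of a surviving edge. When the input list is named,
#' each edge carries a \code{sources} attribute listing the tables that
#' contributed it.
#'
#' @param tables a single data.frame (as from \code{\link{loadEdgeTable}})
#'   or a list of them; each needs columns \code{from} and \code{to}
#' @return a \linkS4class{PINetwork}
#' @examples
#' t1 <- data.frame(from = c("A", "B"), to = c("B", "C"))
#' t2 <- data.frame(from = c("B", "A"), to = c("A", "A"))
#' buildPIN(list(t1, t2))
#' @export
buildPIN <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) return(emptyPIN())
  nm <- names(tables)
  if (is.null(nm)) nm <- rep("", length(tables))
  pieces <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    if (!nrow(tb)) return(NULL)
    data.frame(from = as.character(tb$from), to = as.character(tb$to),
               source = nm[i], stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  if (is.null(all) || !nrow(all)) return(emptyPIN())
  all <- all[all$from != all$to, , drop = FALSE]
  if (!nrow(all)) return(emptyPIN())
  a <- pmin(all$from, all$to)
  b <- pmax(all$from, all$to)
  key <- paste(a, b, sep = "\r")
  src <- vapply(split(all$source, key), function(s)
    paste(sort(unique(s[nzchar(s)])), collapse = ","), "")
  uk <- names(src)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      to   = vapply(parts, `[[`, "", 2L),
                      sources = unname(src), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  methods::new("PINetwork", graph = g)
}

emptyPIN <- function() {
  methods::new("PINetwork", graph = igraph::make_empty_graph(0, directed = FALSE))
}

#' Construct a PINetwork from an igraph or edge data.frame
#'
#' Convenience constructor used by the simulator and tests: accepts an
#' undirected igraph (simplified on the way in) or a two-column edge
#' data.frame plus an optional isolated-vertex list.
#'
#' @param x an igraph object or a data.frame with columns from/to
#' @param vertices optional character vector of all vertex names (to keep
#'   isolated nodes)
#' @return a \linkS4class{PINetwork}
#' @export
asPINetwork <- function(x, vertices = NULL) {
  if (igraph::is_igraph(x)) {
    g <- igraph::as_undirected(x, mode = "collapse")
    g <- igraph::simplify(g)
    if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
      igraph::V(g)$name <- sprintf("v%03d", seq_len(igraph::vcount(g)))
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(x$from), to = as.character(x$to)),
      directed = FALSE, vertices = vertices)
    g <- igraph::simplify(g)
  }
  methods::new("PINetwork", graph = g)
}

#' @describeIn geneIds gene identifiers of a PINetwork
#' @export
setMethod("geneIds", "PINetwork", function(x) {
  n <- igraph::vcount(x@graph)
  if (n == 0) character() else igraph::V(x@graph)$name
})

#' @describeIn numEdges edge count of a PINetwork
#' @export
setMethod("numEdges", "PINetwork", function(x) igraph::ecount(x@graph))

#' @describeIn networkDensity density of a PINetwork
#' @export
setMethod("networkDensity", "PINetwork", function(x) {
  n <- igraph::vcount(x@graph)
  if (n <= 1) return(0)
  2 * igraph::ecount(x@graph) / (n * (n - 1))
})

#' Edge density from printed node and edge counts
#'
#' The density of an undirected simple graph depends only on its node and
#' edge counts: \eqn{2E/(N(N-1))}. This helper recomputes a reported
#' density from published counts without needing the graph itself.
#'
#' @param nNodes node count (N)
#' @param nEdges edge count (E)
#' @return density in [0, 1]; 0 by convention when \code{nNodes <= 1}
#' @examples
#' edgeDensityFromCounts(10632, 85019)  # ~0.0015
#' @export
edgeDensityFromCounts <- function(nNodes, nEdges) {
  if (nNodes <= 1) return(0)
  if (nEdges < 0 || nEdges > nNodes * (nNodes - 1) / 2)
    stop("inconsistent node/edge counts")
  2 * nEdges / (nNodes * (nNodes - 1))
}

#' Topology metrics of an induced sub-network
#'
#' Computes, on the subgraph induced by a gene set, the four metrics used
#' throughout the modularity analysis: size of the largest connected
#' component (LCC), number of edges within the gene set, edge density, and
#' the average shortest path over unordered node pairs of the LCC only.
#' Genes absent from the network are dropped with a warning (mirroring how
#' screen seed genes missing from the PIN are handled).
#'
#' @param net a \linkS4class{PINetwork}
#' @param genes character vector of gene identifiers
#' @return list with \code{lcc_size}, \code{n_edges}, \code{density} and
#'   \code{avg_shortest_path} (\code{NA} when the LCC has fewer than two
#'   nodes, i.e. the path average is undefined)
#' @examples
#' net <- asPINetwork(data.frame(from = c("A", "B", "C"),
#'                               to   = c("B", "C", "A")))
#' subnetworkMetrics(net, c("A", "B", "C"))
#' @export
subnetworkMetrics <- function(net, genes) {
  genes <- unique(as.character(genes))
  present <- intersect(genes, geneIds(net))
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " gene(s) absent from the network were dropped")
  if (!length(present))
    return(list(lcc_size = 0L, n_edges = 0L, density = 0,
                avg_shortest_path = NA_real_))
  sub <- igraph::induced_subgraph(net@graph, present)
  n <- igraph::vcount(sub)
  e <- igraph::ecount(sub)
  comp <- igraph::components(sub)
  lcc_nodes <- largestComponent(sub, comp)
  lcc_size <- length(lcc_nodes)
  dens <- if (n <= 1) 0 else 2 * e / (n * (n - 1))
  asp <- NA_real_
  if (lcc_size >= 2) {
    lsub <- igraph::induced_subgraph(sub, lcc_nodes)
    d <- igraph::distances(lsub)
    asp <- mean(d[upper.tri(d)])
  }
  list(lcc_size = as.integer(lcc_size), n_edges = as.integer(e),
       density = dens, avg_shortest_path = asp)
}

# Largest component of an igraph; ties broken by the component whose
# lexicographically smallest member sorts first (deterministic).
largestComponent <- function(g, comp = igraph::components(g)) {
  if (comp$no == 0) return(character())
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  nm <- igraph::V(g)$name
  if (length(best) > 1) {
    mins <- vapply(best, function(k) min(nm[comp$membership == k]), "")
    best <- best[order(mins)][1L]
  }
  nm[comp$membership == best]
}

#' Write a network as a canonical edge-list TSV
#'
#' Endpoints of each edge are ordered lexicographically and rows are sorted,
#' so the output is bit-exact across runs for the same network.
#'
#' @param net a \linkS4class{PINetwork}
#' @param path output file path
#' @return invisibly, the path
#' @export
writePIN <- function(net, path) {
  el <- igraph::as_edgelist(net@graph)
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    df <- data.frame(gene_a = a[o], gene_b = b[o])
  } else {
    df <- data.frame(gene_a = character(), gene_b = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network written by \code{writePIN}
#'
#' @param path path to a two-column TSV with a header row
#' @return a \linkS4class{PINetwork}
#' @export
readPIN <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  asPINetwork(data.frame(from = df[[1]], to = df[[2]]))
}

#' Export a network to GraphML
#'
#' @param net a \linkS4class{PINetwork}
#' @param path output file path
#' @return invisibly, the path
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(net@graph, path, format = "graphml")
  invisible(path)
}
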