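#' Four centrality metrics for every gene in a network
#'
#' Computes the centrality measures used to rank genes for phenotype
#' prediction:
#' \describe{
#'   \item{degree}{normalised degree, deg(v)/(N-1);}
#'   \item{betweenness}{fraction of shortest paths passing through a gene,
#'     endpoints excluded, normalised by (N-1)(N-2)/2;}
#'   \item{closeness}{reachable-set closeness with Wasserman-Faust scaling:
#'     for a node reaching r other nodes at total distance D, closeness is
#'     (r/(N-1)) * (r/D); isolated nodes score 0. Defined for every node of
#'     a disconnected graph;}
#'   \item{eigenvector}{leading eigenvector of the adjacency matrix via
#'     power iteration (tolerance 1e-10, at most 1000 iterations),
#'     L2-normalised; nodes outside the dominant component may receive
#'     values near zero.}
#' }
#'
#' @param net a \linkS4class{PINetwork} with at least 2 nodes
#' @return data.frame with columns \code{gene}, \code{degree},
#'   \code{betweenness}, \code{closeness}, \code{eigenvector}, one row per
#'   network node
#' @examples
#' star <- asPINetwork(data.frame(from = "h", to = c("a", "b", "c")))
#' computeCentralities(star)
#' @export
computeCentralities <- function(net) {
  g <- net@graph
  n <- igraph::vcount(g)
  if (n < 2) stop("centralities need a network with at least 2 nodes")
  genes <- igraph::V(g)$name
  deg <- igraph::degree(g) / (n - 1)
  btw <- igraph::betweenness(g, normalized = TRUE)
  clo <- closenessWF(g)
  eig <- eigenvectorPower(g)
  data.frame(gene = genes, degree = unname(deg),
             betweenness = unname(btw), closeness = unname(clo),
             eigenvector = unname(eig), stringsAsFactors = FALSE)
}

# Wasserman-Faust closeness: per-node, over its reachable set only, scaled
# by (reachable-1)/(N-1) so scores are comparable across components.
closenessWF <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  diag(d) <- NA
  vapply(seq_len(n), function(i) {
    di <- d[i, ]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
}

# Power iteration for the leading adjacency eigenvector; deterministic
# uniform start, L2-normalised output, absolute values (Perron vector).
# Iterates on A + I so the dominant eigenvalue is strictly positive and
# the iteration cannot oscillate on bipartite graphs; the eigenvector of
# A + I equals that of A.
eigenvectorPower <- function(g, tol = 1e-10, maxIter = 1000L) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(maxIter)) {
    y <- as.numeric(A %*% x) + x
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(rep(0, n))
    y <- y / ny
    if (max(abs(y - x)) < tol) {
      if (igraph::ecount(g) == 0) return(rep(0, n))  # edgeless graph
      return(abs(y))
    }
    x <- y
  }
  stop("eigenvector centrality did not converge after ", maxIter,
       " iterations")
}

#' Area under the ROC curve of a gene score against a binary outcome
#'
#' Computes the AUC in its rank-statistic (Mann-Whitney) form: the
#' probability that a randomly chosen positive gene scores higher than a
#' randomly chosen negative gene, with half credit for ties. Used to ask
#' whether a centrality measure predicts screen positivity; an AUC above
#' 0.5 indicates positive correlation, below 0.5 negative.
#'
#' @param score numeric vector of per-gene scores
#' @param outcome logical (or 0/1) vector of the same length; both classes
#'   must be present
#' @return AUC in [0, 1]
#' @examples
#' rocAUC(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' rocAUC(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))  # 0.5
#' @export
rocAUC <- function(score, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(score) == length(outcome))
  keep <- !is.na(score) & !is.na(outcome)
  score <- score[keep]; outcome <- outcome[keep]
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present to compute an AUC")
  r <- rank(score)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
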