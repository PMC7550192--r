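# The meta network unites the four phenotypic sub-networks and bins genes
# into the seven non-empty regions of the three-screen Venn diagram.
metaGroupTable <- function() {
  data.frame(
    group = c("I", "II", "III", "IV", "V", "VI", "VII"),
    hpo_egg_laying = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    egg_laying     = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    hpo_ovariole   = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

signatureToGroup <- function(hpoEgg, egg, hpoOva) {
  tab <- metaGroupTable()
  hit <- tab$hpo_egg_laying == hpoEgg & tab$egg_laying == egg &
    tab$hpo_ovariole == hpoOva
  if (!any(hit)) stop("a meta-network gene must carry at least one phenotype flag")
  tab$group[hit]
}

#' Assign meta-network genes to the seven phenotype groups
#'
#' The meta network is the union of the four sub-networks (seeds plus
#' connectors). Each gene receives a phenotype signature — three booleans,
#' one per screen — and lands in exactly one of the seven Venn-region
#' groups: I = sensitised (hpo) egg laying only, II = egg laying only,
#' III = hpo ovariole only, IV = all three (the core region), V = hpo egg
#' laying + hpo ovariole, VI = egg laying + hpo ovariole, VII = hpo egg
#' laying + egg laying.
#'
#' Seeds take their screen-positivity signature. Connectors take the
#' phenotype signature of the sub-network(s) that predicted them (the
#' union when several did; the core sub-network carries all three flags).
#' A gene that is a seed in one sub-network and a connector in another
#' combines both sources into a single signature, and keeps the "seed"
#' role.
#'
#' @param scaResults named list of \linkS4class{SCAResult} objects; names
#'   must include "core", "hpo_egg_laying", "egg_laying", "hpo_ovariole"
#' @param calls data.frame with columns \code{screen}, \code{gene},
#'   \code{call} (as consumed by \code{\link{buildSeedLists}}), providing
#'   the per-screen positivity of the seed genes
#' @param includeConnectors logical; when \code{FALSE}, only seed genes
#'   are grouped (the seed-only contrast analysis)
#' @return data.frame with columns \code{gene}, \code{role} ("seed" or
#'   "connector"), \code{hpo_egg_laying}, \code{egg_laying},
#'   \code{hpo_ovariole} (logical signature) and \code{group}
#' @export
assignMetaGroups <- function(scaResults, calls, includeConnectors = TRUE) {
  needed <- c("core", "hpo_egg_laying", "egg_laying", "hpo_ovariole")
  if (!all(needed %in% names(scaResults)))
    stop("scaResults must be named: ", paste(needed, collapse = ", "))
  screens <- c("hpo_egg_laying", "egg_laying", "hpo_ovariole")
  netSig <- rbind(
    core           = c(TRUE, TRUE, TRUE),
    hpo_egg_laying = c(TRUE, FALSE, FALSE),
    egg_laying     = c(FALSE, TRUE, FALSE),
    hpo_ovariole   = c(FALSE, FALSE, TRUE)
  )
  colnames(netSig) <- screens

  allSeeds <- unique(unlist(lapply(scaResults, seedGenes)))
  allConn <- unique(unlist(lapply(scaResults, connectors)))
  pureConn <- setdiff(allConn, allSeeds)
  genes <- if (includeConnectors) union(allSeeds, pureConn) else allSeeds

  sig <- matrix(FALSE, length(genes), 3,
                dimnames = list(genes, screens))
  # seeds: screen positivity from the calls table
  pos <- calls[calls$call != "none", , drop = FALSE]
  for (s in screens) {
    hits <- intersect(genes, as.character(pos$gene[pos$screen == s]))
    sig[hits, s] <- TRUE
  }
  # connectors: union of predicting sub-networks' signatures
  for (nw in needed) {
    cn <- intersect(connectors(scaResults[[nw]]), genes)
    if (length(cn))
      sig[cn, ] <- sig[cn, , drop = FALSE] | rep(netSig[nw, ], each = length(cn))
  }
  group <- vapply(seq_along(genes), function(i)
    signatureToGroup(sig[i, 1], sig[i, 2], sig[i, 3]), "")
  data.frame(gene = genes,
             role = ifelse(genes %in% allSeeds, "seed", "connector"),
             hpo_egg_laying = sig[, 1], egg_laying = sig[, 2],
             hpo_ovariole = sig[, 3], group = group,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise edge densities between gene groups
#'
#' Counts network edges with one endpoint in each group of a partition and
#' normalises: between groups g and h the density is
#' edges/(n_g * n_h); within a group it is edges/(n(n-1)/2). Pairs
#' involving an empty group, and single-gene diagonals, are undefined
#' (\code{NA}), never reported as zero.
#'
#' @param net a \linkS4class{PINetwork}
#' @param groups data.frame with columns \code{gene} and \code{group};
#'   genes must be disjoint across groups and present in the network
#' @return data.frame with one row per unordered group pair (diagonal
#'   included): \code{group_a}, \code{group_b}, \code{edges}, \code{n_a},
#'   \code{n_b}, \code{density}
#' @export
pairwiseEdgeDensity <- function(net, groups) {
  gene <- as.character(groups$gene)
  if (anyDuplicated(gene)) stop("groups must be disjoint (duplicated gene)")
  if (!all(gene %in% geneIds(net)))
    stop("all grouped genes must be present in the network")
  lab <- as.character(groups$group)
  ids <- sort(unique(lab))
  memb <- stats::setNames(lab, gene)
  sub <- igraph::induced_subgraph(net@graph, gene)
  el <- igraph::as_edgelist(sub)
  ga <- memb[el[, 1]]; gb <- memb[el[, 2]]
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  cnt <- table(factor(paste(lo, hi, sep = "\r"),
                      levels = {
                        pr <- expand.grid(a = ids, b = ids,
                                          stringsAsFactors = FALSE)
                        pr <- pr[pr$a <= pr$b, ]
                        paste(pr$a, pr$b, sep = "\r")
                      }))
  size <- table(factor(lab, levels = ids))
  pr <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  na <- as.integer(size[pr[, 1]]); nb <- as.integer(size[pr[, 2]])
  edges <- as.integer(cnt)
  dens <- ifelse(pr[, 1] == pr[, 2],
                 ifelse(na >= 2, edges / (na * (na - 1) / 2), NA_real_),
                 ifelse(na >= 1 & nb >= 1, edges / (na * nb), NA_real_))
  data.frame(group_a = pr[, 1], group_b = pr[, 2], edges = edges,
             n_a = na, n_b = nb, density = dens,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Label-permutation Z scores of group edge densities
#'
#' Builds a null by randomly reassigning the grouped genes to groups of
#' the observed sizes, recomputing the pairwise edge densities each time.
#' The Z score of a pair is (observed density - null mean)/null sd;
#' pairs whose null sd is zero (or whose density is undefined) are
#' \code{NA}.
#'
#' @param net a \linkS4class{PINetwork}
#' @param groups data.frame with columns \code{gene}, \code{group}
#' @param nPermutations number of label permutations (default 1000)
#' @return the observed density table (see
#'   \code{\link{pairwiseEdgeDensity}}) with extra columns
#'   \code{null_mean}, \code{null_sd}, \code{z}
#' @export
groupPermutationZ <- function(net, groups, nPermutations = 1000L) {
  if (length(unique(groups$group)) < 2L)
    stop("at least two groups are needed for a permutation test")
  obs <- pairwiseEdgeDensity(net, groups)
  null <- matrix(NA_real_, nPermutations, nrow(obs))
  perm <- groups
  for (i in seq_len(nPermutations)) {
    perm$group <- sample(groups$group)
    null[i, ] <- pairwiseEdgeDensity(net, perm)$density
  }
  nm <- colMeans(null)
  nsd <- apply(null, 2, stats::sd)
  obs$null_mean <- nm
  obs$null_sd <- nsd
  obs$z <- ifelse(!is.na(nsd) & nsd > 0 & !is.na(obs$density),
                  (obs$density - nm) / nsd, NA_real_)
  obs
}

#' Pathway composition of gene groups
#'
#' For every group and pathway, the fraction of group members annotated to
#' the pathway. Genes may belong to several pathways, so a group's
#' fractions can sum to more than one.
#'
#' @param groups data.frame with columns \code{gene}, \code{group}; all
#'   groups must be non-empty
#' @param annotation named list mapping pathway name to member genes
#' @return data.frame \code{group}, \code{pathway}, \code{members},
#'   \code{group_size}, \code{fraction}
#' @export
pathwayProportions <- function(groups, annotation) {
  if (!nrow(groups)) stop("empty group table")
  ids <- sort(unique(as.character(groups$group)))
  out <- do.call(rbind, lapply(ids, function(gid) {
    members <- as.character(groups$gene[groups$group == gid])
    if (!length(members)) stop("group '", gid, "' is empty")
    m <- vapply(annotation, function(p) length(intersect(members, p)), 1L)
    data.frame(group = gid, pathway = names(annotation), members = m,
               group_size = length(members), fraction = m / length(members),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}
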