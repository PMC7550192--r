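# Synthetic study generator: protein networks with planted dense modules and
# planted connector hubs, batch-structured screen measurements with known
# per-gene effects, and overlapping pathway annotations. Every stage of the
# pipeline can be validated against this ground truth.

#' Configuration for a synthetic study
#'
#' Default values mirror the design of the screens the package analyses:
#' 463 candidate genes screened in batches of ~50, five control vials of
#' three females per batch for egg laying, 20 control flies (40 ovaries)
#' per batch for ovariole number, one candidate vial and 20 candidate
#' ovaries per gene, thresholds applied downstream of 1 (primary), 5 (egg)
#' and 2 (ovariole). Egg counts are negative-binomial per day (counts are
#' integer and over-dispersed; dispersion \code{Inf} gives Poisson);
#' ovariole counts are rounded Gaussians truncated at zero. True effects
#' are expressed in units of the control standard deviation of the
#' phenotype's measurement unit, so recovery targets are scale-free.
#'
#' The planted interactome holds the screened genes plus extra untested
#' nodes: hit genes form dense modules, consecutive modules are joined
#' only through planted connector hubs (background edges directly linking
#' two modules are suppressed so the clusters are otherwise separate), and
#' everything else is sparse background.
#'
#' @param nGenes number of screened candidate genes
#' @param genesPerBatch batch size for candidate genes
#' @param controlVials control egg-laying vials per batch
#' @param controlFlies control flies per batch for ovarioles (two ovaries
#'   each)
#' @param candidateOvaries scored ovaries per candidate gene
#' @param eggDayMean control mean eggs per vial per day
#' @param eggDispersion negative-binomial size parameter (Inf = Poisson)
#' @param ovarioleMean control mean ovarioles per ovary
#' @param ovarioleSd control per-ovary standard deviation
#' @param deathRate probability a vial is lost to a fly death
#' @param moduleSizes sizes of the planted modules; their members are the
#'   true hit genes
#' @param withinDensity edge density inside each planted module
#' @param hitEffect true shift of module genes, in control-sd units,
#'   applied to both phenotypes
#' @param nExtraNodes untested background nodes added to the interactome
#' @param backgroundDensity background edge probability
#' @param connectorAttach planted edges from a connector into each of its
#'   two modules
#' @param nPathways,pathwaySizeRange,pathwayOverlap pathway annotation
#'   spec: number of pathways, size range, and the fraction of each
#'   pathway drawn from already-annotated genes (0 = pairwise disjoint)
#' @return a list of class \code{synthConfig}
#' @export
synthConfig <- function(nGenes = 463L, genesPerBatch = 50L,
                        controlVials = 5L, controlFlies = 20L,
                        candidateOvaries = 20L,
                        eggDayMean = 60, eggDispersion = 10,
                        ovarioleMean = 20, ovarioleSd = 2.5,
                        deathRate = 0.02,
                        moduleSizes = c(15L, 12L, 10L),
                        withinDensity = 0.8, hitEffect = -8,
                        nExtraNodes = 40L, backgroundDensity = 0.004,
                        connectorAttach = 3L,
                        nPathways = 14L, pathwaySizeRange = c(12L, 45L),
                        pathwayOverlap = 0.15) {
  stopifnot(nGenes >= 1, genesPerBatch >= 1, controlVials >= 2,
            controlFlies >= 1, candidateOvaries >= 1,
            eggDayMean > 0, eggDispersion > 0,
            ovarioleMean > 0, ovarioleSd > 0,
            deathRate >= 0, deathRate < 1,
            all(moduleSizes >= 1), withinDensity >= 0, withinDensity <= 1,
            backgroundDensity >= 0, backgroundDensity <= 1,
            sum(moduleSizes) <= nGenes)
  structure(as.list(environment()), class = "synthConfig")
}

geneNames <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a protein-interaction network with planted structure
#'
#' Builds a sparse background random graph and plants dense modules joined
#' only through connector hub nodes: each connector is adjacent to several
#' members of each of two consecutive modules, while background edges that
#' would directly link two modules are suppressed, so the planted clusters
#' are otherwise separate. Each module is generated connected (a spanning
#' path is laid down before density edges). No self-loops or duplicate
#' edges are produced.
#'
#' @param config a \code{\link{synthConfig}}; fields used: moduleSizes,
#'   withinDensity, nGenes, nExtraNodes, backgroundDensity,
#'   connectorAttach
#' @param seed integer RNG seed (optional; the caller may seed instead)
#' @param moduleGenes optional list of character vectors naming the module
#'   members explicitly (defaults to the first hit genes of the screen
#'   universe)
#' @return list with \code{net} (a \linkS4class{PINetwork}) and
#'   \code{truth}: data.frame \code{gene}, \code{module} (index or NA),
#'   \code{is_connector}
#' @export
simulatePIN <- function(config = synthConfig(), seed = NULL,
                        moduleGenes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- as.integer(config$moduleSizes)
  nMod <- length(sizes)
  if (is.null(moduleGenes)) {
    screened <- geneNames(config$nGenes)
    moduleGenes <- split(screened[seq_len(sum(sizes))],
                         rep(seq_len(nMod), sizes))
    rest <- screened[-seq_len(sum(sizes))]
  } else {
    stopifnot(length(moduleGenes) == nMod)
    rest <- setdiff(geneNames(config$nGenes), unlist(moduleGenes))
  }
  nConn <- max(0L, nMod - 1L)
  connNames <- if (nConn) sprintf("C%02d", seq_len(nConn)) else character()
  extra <- if (config$nExtraNodes)
    sprintf("N%04d", seq_len(config$nExtraNodes)) else character()
  allNodes <- c(unlist(moduleGenes), connNames, rest, extra)
  modOf <- rep(NA_integer_, length(allNodes))
  names(modOf) <- allNodes
  for (m in seq_len(nMod)) modOf[moduleGenes[[m]]] <- m
  isConn <- allNodes %in% connNames

  edges <- list()
  # planted modules: spanning path for connectedness, then density edges
  for (m in seq_len(nMod)) {
    mem <- moduleGenes[[m]]
    if (length(mem) >= 2) {
      perm <- sample(mem)
      edges[[length(edges) + 1L]] <-
        cbind(perm[-length(perm)], perm[-1])
      pairs <- utils::combn(sort(mem), 2)
      keep <- stats::runif(ncol(pairs)) < config$withinDensity
      if (any(keep))
        edges[[length(edges) + 1L]] <- t(pairs[, keep, drop = FALSE])
    }
  }
  # planted connectors chain consecutive modules
  if (nConn) {
    for (k in seq_len(nConn)) {
      for (m in c(k, k + 1L)) {
        mem <- moduleGenes[[m]]
        att <- sample(mem, min(config$connectorAttach, length(mem)))
        edges[[length(edges) + 1L]] <- cbind(connNames[k], att)
      }
    }
  }
  # sparse background everywhere else; suppressed where it would directly
  # join two modules, or attach a connector beyond its planted edges
  bgNodes <- allNodes[!isConn]
  if (length(bgNodes) >= 2 && config$backgroundDensity > 0) {
    pairs <- utils::combn(bgNodes, 2)
    m1 <- modOf[pairs[1, ]]; m2 <- modOf[pairs[2, ]]
    sameClass <- !is.na(m1) & !is.na(m2)  # module-module pairs
    eligible <- !(sameClass)              # covers same & different modules
    keep <- eligible & stats::runif(ncol(pairs)) < config$backgroundDensity
    if (any(keep)) {
      bg <- pairs[, keep, drop = FALSE]
      # keep the clusters otherwise-separate: a background node may touch
      # members of at most one module (its lowest-indexed one), so no
      # chance node can bridge two clusters the way a planted hub does
      bgm <- rbind(modOf[bg[1, ]], modOf[bg[2, ]])
      touches <- data.frame(node = c(bg[1, ], bg[2, ]),
                            mod = c(bgm[2, ], bgm[1, ]))
      touches <- touches[!is.na(touches$mod), , drop = FALSE]
      firstMod <- vapply(split(touches$mod, touches$node), min, 0)
      dropEdge <- logical(ncol(bg))
      for (r in 1:2) {
        other <- bgm[3 - r, ]
        hasMod <- !is.na(other)
        dropEdge <- dropEdge |
          (hasMod & firstMod[bg[r, ]] != other & !is.na(firstMod[bg[r, ]]))
      }
      dropEdge[is.na(dropEdge)] <- FALSE
      bg <- bg[, !dropEdge, drop = FALSE]
      if (ncol(bg))
        edges[[length(edges) + 1L]] <- t(bg)
    }
  }
  el <- do.call(rbind, edges)
  df <- if (is.null(el)) data.frame(from = character(), to = character())
        else data.frame(from = el[, 1], to = el[, 2])
  net <- asPINetwork(df, vertices = allNodes)
  truth <- data.frame(gene = allNodes, module = unname(modOf),
                      is_connector = isConn,
                      stringsAsFactors = FALSE)
  list(net = net, truth = truth)
}

rEggDay <- function(n, mu, size) {
  mu <- pmax(mu, 1e-3)
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, size = size, mu = mu)
}

rOvary <- function(n, mu, sd) pmax(0, round(stats::rnorm(n, mu, sd)))

# model-implied control sd of a 5-day vial total (the "control sd" unit
# for egg-laying effects)
eggTotalSd <- function(config) {
  mu <- config$eggDayMean; size <- config$eggDispersion
  v <- if (is.infinite(size)) mu else mu + mu^2 / size
  sqrt(5 * v)
}

#' Simulate the three phenotype screens
#'
#' Generates raw measurement tables for the sensitised egg-laying screen,
#' the wild-type egg-laying screen and the sensitised ovariole screen over
#' the full candidate list, with batch structure: per batch, control vials
#' and control ovaries from the noise model, one candidate vial and
#' \code{candidateOvaries} ovaries per candidate gene. True effects (in
#' control-sd units of the phenotype's measurement unit) shift the
#' generating mean; vial-death events occur at \code{deathRate} and mark
#' the vial for exclusion.
#'
#' @param config a \code{\link{synthConfig}}
#' @param seed integer RNG seed (optional)
#' @param effectTable optional data.frame \code{gene}, \code{egg},
#'   \code{ovariole} of true shifts; defaults to \code{hitEffect} on both
#'   phenotypes for the planted module genes and zero elsewhere
#' @return list with \code{eggs} (screen_id, gene_id, batch_id, vial_id,
#'   day1..day5, death_flag), \code{ovarioles} (screen_id, gene_id,
#'   batch_id, fly_id, ovary_id, ovariole_count) and \code{truth} (gene,
#'   batch, egg, ovariole)
#' @export
simulateScreens <- function(config = synthConfig(), seed = NULL,
                            effectTable = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- geneNames(config$nGenes)
  if (is.null(effectTable)) {
    nHit <- sum(config$moduleSizes)
    eff <- numeric(config$nGenes)
    eff[seq_len(nHit)] <- config$hitEffect
    effectTable <- data.frame(gene = genes, egg = eff, ovariole = eff,
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(genes %in% effectTable$gene))
  effEgg <- stats::setNames(effectTable$egg, effectTable$gene)[genes]
  effOva <- stats::setNames(effectTable$ovariole, effectTable$gene)[genes]
  nBatch <- ceiling(config$nGenes / config$genesPerBatch)
  batchOf <- rep(seq_len(nBatch), each = config$genesPerBatch)[seq_len(config$nGenes)]
  batchIds <- sprintf("B%02d", batchOf)
  sdEgg <- eggTotalSd(config)
  eggScreens <- c("hpo_egg_laying", "egg_laying")
  eggs <- list(); ovas <- list()

  for (scr in eggScreens) {
    for (b in seq_len(nBatch)) {
      bid <- sprintf("B%02d", b)
      # batch-specific drift of the control mean (the batch effect the
      # Z standardisation exists to remove)
      muDay <- config$eggDayMean + stats::rnorm(1, 0, 0.1 * config$eggDayMean)
      ctl <- do.call(rbind, lapply(seq_len(config$controlVials), function(v)
        data.frame(screen_id = scr, gene_id = "CONTROL", batch_id = bid,
                   vial_id = sprintf("%s_ctl_%02d", bid, v),
                   t(stats::setNames(rEggDay(5, muDay, config$eggDispersion),
                                     paste0("day", 1:5))),
                   death_flag = stats::runif(1) < config$deathRate,
                   stringsAsFactors = FALSE)))
      gset <- genes[batchOf == b]
      cand <- do.call(rbind, lapply(gset, function(g)
        data.frame(screen_id = scr, gene_id = g, batch_id = bid,
                   vial_id = sprintf("%s_%s", bid, g),
                   t(stats::setNames(
                     rEggDay(5, muDay + effEgg[g] * sdEgg / 5,
                             config$eggDispersion),
                     paste0("day", 1:5))),
                   death_flag = stats::runif(1) < config$deathRate,
                   stringsAsFactors = FALSE)))
      eggs[[length(eggs) + 1L]] <- rbind(ctl, cand)
    }
  }
  for (b in seq_len(nBatch)) {
    bid <- sprintf("B%02d", b)
    muOva <- config$ovarioleMean + stats::rnorm(1, 0, 0.5 * config$ovarioleSd)
    ctl <- do.call(rbind, lapply(seq_len(config$controlFlies), function(f)
      data.frame(screen_id = "hpo_ovariole", gene_id = "CONTROL",
                 batch_id = bid, fly_id = sprintf("%s_ctl_%02d", bid, f),
                 ovary_id = c("L", "R"),
                 ovariole_count = rOvary(2, muOva, config$ovarioleSd),
                 stringsAsFactors = FALSE)))
    gset <- genes[batchOf == b]
    cand <- do.call(rbind, lapply(gset, function(g) {
      nOv <- config$candidateOvaries
      data.frame(screen_id = "hpo_ovariole", gene_id = g, batch_id = bid,
                 fly_id = sprintf("%s_%s_f%02d", bid, g,
                                  rep(seq_len(ceiling(nOv / 2)), each = 2)[seq_len(nOv)]),
                 ovary_id = rep(c("L", "R"), length.out = nOv),
                 ovariole_count = rOvary(nOv, muOva + effOva[g] * config$ovarioleSd,
                                         config$ovarioleSd),
                 stringsAsFactors = FALSE)
    }))
    ovas[[length(ovas) + 1L]] <- rbind(ctl, cand)
  }
  list(eggs = do.call(rbind, eggs),
       ovarioles = do.call(rbind, ovas),
       truth = data.frame(gene = genes, batch = batchIds,
                          egg = unname(effEgg), ovariole = unname(effOva),
                          stringsAsFactors = FALSE))
}

#' Simulate overlapping pathway annotations
#'
#' Draws pathways of configured sizes over a gene universe. A fraction
#' \code{overlapRate} of each pathway's members is drawn from genes
#' already annotated to some pathway (so genes may belong to several
#' pathways); at \code{overlapRate = 0} the pathways are pairwise
#' disjoint.
#'
#' @param genes character gene universe
#' @param nPathways number of pathways
#' @param sizeRange inclusive size range (length-2 integer)
#' @param overlapRate fraction in [0, 1)
#' @param seed integer RNG seed (optional)
#' @return list with \code{annotation} (named list pathway -> genes) and
#'   \code{truth} (data.frame gene, pathway; one row per membership)
#' @export
simulatePathways <- function(genes, nPathways = 14L,
                             sizeRange = c(15L, 60L), overlapRate = 0.1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(overlapRate >= 0, overlapRate < 1,
            sizeRange[1] >= 1, sizeRange[2] >= sizeRange[1],
            sizeRange[2] <= length(genes))
  unused <- genes
  annotation <- list()
  sizeChoices <- seq(sizeRange[1], sizeRange[2])
  for (i in seq_len(nPathways)) {
    size <- sizeChoices[sample.int(length(sizeChoices), 1)]
    nOld <- min(floor(size * overlapRate),
                length(setdiff(genes, unused)))
    nNew <- size - nOld
    if (nNew > length(unused)) {
      # overlapRate sets the minimum sharing; once the unannotated pool is
      # exhausted, further members must be shared. At overlap 0 the
      # pathways are required disjoint, so exhaustion is an error.
      if (overlapRate == 0)
        stop("infeasible pathway spec: gene universe exhausted at pathway ", i)
      nOld <- nOld + (nNew - length(unused))
      nNew <- length(unused)
    }
    new <- if (nNew) sample(unused, nNew) else character()
    oldPool <- setdiff(genes, c(unused, new))
    if (nOld > length(oldPool))
      stop("infeasible pathway spec: pathway ", i,
           " larger than the gene universe")
    old <- if (nOld) sample(oldPool, nOld) else character()
    annotation[[sprintf("pathway_%02d", i)]] <- sort(c(new, old))
    unused <- setdiff(unused, new)
  }
  truth <- do.call(rbind, lapply(names(annotation), function(p)
    data.frame(gene = annotation[[p]], pathway = p,
               stringsAsFactors = FALSE)))
  list(annotation = annotation, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' One call producing everything the pipeline consumes, with consistent
#' ground truth: the planted interactome (module members are the true hit
#' genes, chained by planted connectors), the three raw screen tables, and
#' pathway annotations over the screened genes.
#'
#' @param config a \code{\link{synthConfig}}
#' @param seed integer seed controlling all randomness
#' @return list with \code{net}, \code{pinTruth}, \code{eggs},
#'   \code{ovarioles}, \code{effectTruth}, \code{annotation},
#'   \code{pathwayTruth} and the \code{config} used
#' @export
simulateStudy <- function(config = synthConfig(), seed = 1L) {
  set.seed(seed)
  pin <- simulatePIN(config)
  scr <- simulateScreens(config)
  pw <- simulatePathways(geneNames(config$nGenes), config$nPathways,
                         config$pathwaySizeRange, config$pathwayOverlap)
  list(net = pin$net, pinTruth = pin$truth,
       eggs = scr$eggs, ovarioles = scr$ovarioles,
       effectTruth = scr$truth,
       annotation = pw$annotation, pathwayTruth = pw$truth,
       config = config)
}
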