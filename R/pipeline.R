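# One-call orchestration of the whole analysis: Z scores -> phenotype calls
# and seed lists -> pathway enrichment -> centrality/ROC -> modularity nulls
# -> Seed Connector Algorithm (x4 seed lists) -> meta network. Every stage
# writes plain TSV outputs to the run directory and is recorded, with file
# digests, in a machine-readable manifest.

#' Pipeline configuration
#'
#' Collects inputs (either file paths or a synthetic study spec),
#' thresholds and sampling parameters for \code{\link{runPipeline}}.
#' Thresholds default to the screen design: primary filter |Z| > 1 on the
#' sensitised egg-laying screen, |Z| > 5 for egg-laying calls, |Z| > 2
#' for ovariole calls.
#'
#' @param edges character vector of edge-table paths (ignored when
#'   \code{synth} is given)
#' @param eggs,ovarioles,pathways input TSV paths (ignored when
#'   \code{synth} is given)
#' @param synth optional \code{\link{synthConfig}}: generate the study
#'   instead of reading files
#' @param primaryThreshold,eggThreshold,ovarioleThreshold Z thresholds
#' @param enrichmentSamples Monte-Carlo draws for pathway enrichment
#' @param nullSamples draws for metric null distributions
#' @param permutations label permutations for meta-network densities
#' @param seed integer seed; fanned out per stage so stages are
#'   reproducible independently of execution order
#' @return a list of class \code{pipelineConfig}
#' @export
pipelineConfig <- function(edges = NULL, eggs = NULL, ovarioles = NULL,
                           pathways = NULL, synth = NULL,
                           primaryThreshold = 1, eggThreshold = 5,
                           ovarioleThreshold = 2,
                           enrichmentSamples = 10000L,
                           nullSamples = 1000L, permutations = 1000L,
                           seed = 1L) {
  stopifnot(primaryThreshold > 0, eggThreshold > 0, ovarioleThreshold > 0,
            enrichmentSamples >= 100, nullSamples >= 1, permutations >= 1,
            is.numeric(seed))
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of \code{\link{pipelineConfig}};
#' a \code{synth:} mapping is passed to \code{\link{synthConfig}}.
#'
#' @param path path to a YAML file
#' @return a \code{pipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) y$synth <- do.call(synthConfig, y$synth)
  do.call(pipelineConfig, y)
}

# deterministic per-stage substream of the run seed
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% (2^31 - 1))
}

readPathwayTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  split(df$gene_id, df$pathway)
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full screen-to-network pipeline
#'
#' Executes all stages in order, writing every result table under
#' \code{outDir} and returning (and writing) a run manifest listing stage
#' outputs with MD5 digests, all parameter values and the RNG seed.
#' Identical config and seed reproduce identical digests. Pre-flight
#' validation lists all missing inputs before aborting; a stage failure
#' aborts with the stage name.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @param outDir output directory (created if needed)
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json})
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(config$synth)) {
    paths <- c(config$edges, config$eggs, config$ovarioles, config$pathways)
    if (!length(paths)) stop("config provides neither input paths nor a synthetic spec")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  stages <- list()
  addStage <- function(name, params, outputs) {
    stages[[length(stages) + 1L]] <<- list(stage = name, params = params,
                                           outputs = basename(outputs))
    files <<- c(files, outputs)
  }
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- inputs ----------------------------------------------------------
  if (!is.null(config$synth)) {
    study <- runStage("simulate", simulateStudy(config$synth,
                                                seed = stageSeed(config$seed, "simulate")))
    net <- study$net
    eggs <- study$eggs; ovarioles <- study$ovarioles
    annotation <- study$annotation
    f <- c(writeTSV(study$pinTruth, file.path(outDir, "truth_pin.tsv")),
           writeTSV(study$effectTruth, file.path(outDir, "truth_effects.tsv")))
    addStage("simulate", list(seed = stageSeed(config$seed, "simulate")), f)
  } else {
    tables <- runStage("load_edges",
                       lapply(config$edges, loadEdgeTable))
    names(tables) <- basename(config$edges)
    net <- runStage("build_pin", buildPIN(tables))
    eggs <- utils::read.table(config$eggs, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    ovarioles <- utils::read.table(config$ovarioles, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
    annotation <- readPathwayTable(config$pathways)
    addStage("load_inputs", list(edges = config$edges), character())
  }
  pinPath <- writePIN(net, file.path(outDir, "pin.tsv"))
  addStage("pin", list(nodes = length(geneIds(net)), edges = numEdges(net),
                       density = networkDensity(net)), pinPath)

  # -- Z scores --------------------------------------------------------
  zs <- runStage("zscore", {
    out <- list()
    for (scr in c("hpo_egg_laying", "egg_laying")) {
      sub <- eggs[eggs$screen_id == scr, , drop = FALSE]
      z <- screenZScores(sub, "eggs")
      z$screen <- scr
      out[[scr]] <- z
    }
    sub <- ovarioles[ovarioles$screen_id == "hpo_ovariole", , drop = FALSE]
    z <- screenZScores(sub, "ovarioles")
    z$screen <- "hpo_ovariole"
    out$hpo_ovariole <- z
    out
  })
  # primary filter: only genes with sensitised egg |Z| > threshold go on
  primary <- zs$hpo_egg_laying
  retained <- primary$gene[abs(primary$z) > config$primaryThreshold]
  zTab <- do.call(rbind, lapply(zs, function(d)
    d[d$gene %in% retained, c("screen", "gene", "batch", "x", "z")]))
  rownames(zTab) <- NULL
  f <- writeTSV(zTab, file.path(outDir, "zscores.tsv"))
  addStage("zscore", list(primary_threshold = config$primaryThreshold,
                          n_screened = nrow(primary),
                          n_retained = length(retained)), f)

  # -- calls + seed lists ---------------------------------------------
  thr <- c(hpo_egg_laying = config$eggThreshold,
           egg_laying = config$eggThreshold,
           hpo_ovariole = config$ovarioleThreshold)
  calls <- runStage("calls", {
    do.call(rbind, lapply(names(zs), function(scr) {
      d <- zs[[scr]][zs[[scr]]$gene %in% retained, , drop = FALSE]
      data.frame(screen = scr, gene = d$gene,
                 z = d$z, call = classifyPhenotype(d$z, thr[[scr]]),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(calls) <- NULL
  seeds <- buildSeedLists(calls)
  seedTab <- do.call(rbind, lapply(names(seeds), function(nm)
    if (length(seeds[[nm]]))
      data.frame(list_name = nm, gene = seeds[[nm]])))
  if (is.null(seedTab))
    seedTab <- data.frame(list_name = character(), gene = character())
  f <- c(writeTSV(calls, file.path(outDir, "calls.tsv")),
         writeTSV(seedTab, file.path(outDir, "seeds.tsv")))
  addStage("seeds", as.list(thr), f)

  # -- pathway enrichment ---------------------------------------------
  pool <- sort(unique(unlist(lapply(zs, function(d) d$gene))))
  enrich <- runStage("enrichment", {
    set.seed(stageSeed(config$seed, "enrichment"))
    do.call(rbind, lapply(c("hpo_egg_laying", "egg_laying", "hpo_ovariole"),
      function(scr) {
        pos <- intersect(seeds[[scr]], pool)
        if (!length(pos)) return(NULL)
        e <- pathwaySamplingZ(pos, pool, annotation,
                              nSamples = config$enrichmentSamples)
        cbind(screen = scr, e)
      }))
  })
  if (is.null(enrich)) enrich <- data.frame(screen = character())
  f <- writeTSV(enrich, file.path(outDir, "enrichment.tsv"))
  addStage("enrichment", list(samples = config$enrichmentSamples,
                              pool_size = length(pool)), f)

  # -- centralities + ROC ---------------------------------------------
  cent <- runStage("centrality", computeCentralities(net))
  roc <- runStage("roc", {
    do.call(rbind, lapply(names(zs), function(scr) {
      d <- zs[[scr]][zs[[scr]]$gene %in% retained, , drop = FALSE]
      d <- d[d$gene %in% cent$gene, , drop = FALSE]
      outcome <- abs(d$z) > thr[[scr]]
      if (length(unique(outcome)) < 2) return(NULL)
      idx <- match(d$gene, cent$gene)
      do.call(rbind, lapply(c("degree", "betweenness", "closeness",
                              "eigenvector"), function(mt)
        data.frame(screen = scr, metric = mt,
                   auc = rocAUC(cent[[mt]][idx], outcome),
                   n = nrow(d), stringsAsFactors = FALSE)))
    }))
  })
  if (is.null(roc)) roc <- data.frame(screen = character())
  f <- c(writeTSV(cent, file.path(outDir, "centrality.tsv")),
         writeTSV(roc, file.path(outDir, "roc_auc.tsv")))
  addStage("centrality", list(), f)

  # -- modularity vs null ---------------------------------------------
  modular <- runStage("modularity", {
    set.seed(stageSeed(config$seed, "modularity"))
    screenedInPin <- intersect(pool, geneIds(net))
    do.call(rbind, lapply(names(seeds), function(nm) {
      gs <- intersect(seeds[[nm]], geneIds(net))
      if (length(gs) < 2) return(NULL)
      obs <- suppressWarnings(subnetworkMetrics(net, gs))
      nulls <- metricNullDistribution(net, gs, sampler = "uniform",
                                      pool = screenedInPin,
                                      nSamples = config$nullSamples)
      cbind(gene_set = nm, modularityZ(obs, nulls))
    }))
  })
  if (is.null(modular)) modular <- data.frame(gene_set = character())
  f <- writeTSV(modular, file.path(outDir, "modularity.tsv"))
  addStage("modularity", list(null_samples = config$nullSamples), f)

  # -- Seed Connector Algorithm (x4) ----------------------------------
  sca <- runStage("sca", {
    out <- lapply(seeds, function(gs) suppressWarnings(runSCA(net, gs)))
    names(out) <- names(seeds)
    out
  })
  f <- unlist(lapply(names(sca), function(nm)
    writeSCAResult(sca[[nm]], file.path(outDir, paste0("sca_", nm, ".tsv")))))
  addStage("sca", list(), f)

  # -- meta network ----------------------------------------------------
  meta <- runStage("meta", {
    set.seed(stageSeed(config$seed, "meta"))
    groups <- assignMetaGroups(sca, calls)
    dens <- if (length(unique(groups$group)) >= 2)
      groupPermutationZ(net, groups[, c("gene", "group")],
                        nPermutations = config$permutations)
    else cbind(pairwiseEdgeDensity(net, groups[, c("gene", "group")]),
               null_mean = NA_real_, null_sd = NA_real_, z = NA_real_)
    props <- pathwayProportions(groups[, c("gene", "group")], annotation)
    list(groups = groups, density = dens, proportions = props)
  })
  f <- c(writeTSV(meta$groups, file.path(outDir, "meta_groups.tsv")),
         writeTSV(meta$density, file.path(outDir, "meta_density.tsv")),
         writeTSV(meta$proportions, file.path(outDir, "meta_proportions.tsv")))
  addStage("meta", list(permutations = config$permutations), f)

  # -- manifest --------------------------------------------------------
  digests <- as.list(tools::md5sum(files))
  names(digests) <- basename(files)
  manifest <- list(
    package = "ovanet",
    version = as.character(utils::packageVersion("ovanet")),
    seed = config$seed,
    parameters = list(primary_threshold = config$primaryThreshold,
                      egg_threshold = config$eggThreshold,
                      ovariole_threshold = config$ovarioleThreshold,
                      enrichment_samples = config$enrichmentSamples,
                      null_samples = config$nullSamples,
                      permutations = config$permutations),
    stages = stages,
    files = digests
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a human-readable run report
#'
#' Summarises a completed run from its output tables: per-screen call
#' counts (a Table-2-style layout), seed-list and sub-network sizes, the
#' AUC table and the enriched pathways (fold > 2 and p < 0.05).
#' Regeneration from the same outputs is byte-identical.
#'
#' @param outDir a directory written by \code{\link{runPipeline}}
#' @param path output file (default \code{report.md} inside
#'   \code{outDir})
#' @return invisibly, the report path
#' @export
writeReport <- function(outDir, path = file.path(outDir, "report.md")) {
  rd <- function(f) {
    p <- file.path(outDir, f)
    if (!file.exists(p)) return(NULL)
    tryCatch(utils::read.table(p, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE),
             error = function(e) NULL)
  }
  calls <- rd("calls.tsv"); roc <- rd("roc_auc.tsv")
  enrich <- rd("enrichment.tsv"); groups <- rd("meta_groups.tsv")
  lines <- c("# Screen-to-network pipeline report", "")
  if (!is.null(calls) && nrow(calls)) {
    lines <- c(lines, "## Phenotype calls per screen", "",
               "| screen | negative | none | positive | total |",
               "|---|---|---|---|---|")
    for (scr in unique(calls$screen)) {
      cc <- table(factor(calls$call[calls$screen == scr],
                         levels = c("negative", "none", "positive")))
      lines <- c(lines, sprintf("| %s | %d | %d | %d | %d |", scr,
                                cc["negative"], cc["none"], cc["positive"],
                                sum(cc)))
    }
    lines <- c(lines, "")
  }
  scaFiles <- sort(list.files(outDir, pattern = "^sca_.*\\.tsv$"))
  if (length(scaFiles)) {
    lines <- c(lines, "## Sub-networks (Seed Connector Algorithm)", "",
               "| seed list | seeds | connectors | in final LCC |",
               "|---|---|---|---|")
    for (f in scaFiles) {
      d <- rd(f)
      lines <- c(lines, sprintf("| %s | %d | %d | %d |",
                                sub("^sca_(.*)\\.tsv$", "\\1", f),
                                sum(d$role == "seed"),
                                sum(d$role == "connector"),
                                if (nrow(d)) sum(d$in_final_lcc) else 0L))
    }
    lines <- c(lines, "")
  }
  if (!is.null(roc) && nrow(roc)) {
    lines <- c(lines, "## Centrality ROC AUC", "",
               "| screen | metric | AUC |", "|---|---|---|",
               sprintf("| %s | %s | %.3f |", roc$screen, roc$metric, roc$auc),
               "")
  }
  if (!is.null(enrich) && nrow(enrich)) {
    hits <- enrich[!is.na(enrich$fold) & enrich$fold > 2 & enrich$p < 0.05, ]
    lines <- c(lines, "## Enriched pathways (fold > 2, p < 0.05)", "")
    if (nrow(hits)) {
      lines <- c(lines, "| screen | pathway | fold | p |", "|---|---|---|---|",
                 sprintf("| %s | %s | %.2f | %.3g |", hits$screen,
                         hits$pathway, hits$fold, hits$p))
    } else lines <- c(lines, "none")
    lines <- c(lines, "")
  }
  if (!is.null(groups) && nrow(groups)) {
    cc <- table(groups$group)
    lines <- c(lines, "## Meta-network groups", "",
               "| group | genes |", "|---|---|",
               sprintf("| %s | %d |", names(cc), as.integer(cc)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
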