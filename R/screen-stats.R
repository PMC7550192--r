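#' Five-day egg total of one vial
#'
#' Screen measurements for egg laying are the sum of the eggs laid by the
#' three females of a vial over the five scored days. Vials in which a fly
#' died during the assay are excluded outright (returned as \code{NA}),
#' never zeroed.
#'
#' @param daily numeric vector of five non-negative daily egg counts
#' @param death logical: did a female or male die in this vial?
#' @return integer total, or \code{NA} if the vial is excluded
#' @examples
#' eggTotal(c(3, 4, 5, 6, 7))        # 25
#' eggTotal(c(3, 4, 5, 6, 7), TRUE)  # NA (excluded)
#' @export
eggTotal <- function(daily, death = FALSE) {
  if (length(daily) != 5L) stop("exactly five daily counts expected")
  if (any(daily < 0)) stop("negative egg counts are invalid")
  if (isTRUE(death)) return(NA_integer_)
  as.integer(sum(daily))
}

#' Aggregate ovariole counts of one gene
#'
#' One measurement per gene: the mean ovariole count across that gene's
#' scored ovaries (20 for candidates, each ovary an independent
#' measurement).
#'
#' @param counts numeric vector of non-negative per-ovary ovariole counts
#' @return mean count
#' @examples
#' ovarioleAggregate(c(18, 22))  # 20
#' @export
ovarioleAggregate <- function(counts) {
  if (!length(counts)) stop("no ovary records for this gene")
  if (any(counts < 0)) stop("negative ovariole counts are invalid")
  mean(counts)
}

#' Batch-standardised Z scores
#'
#' Standardises each gene's aggregate measurement against the pooled
#' control measurements of its own batch: \eqn{Z = (x - \mu_b)/\sigma_b},
#' where \eqn{\mu_b} and \eqn{\sigma_b} are the mean and sample standard
#' deviation (n-1 denominator) of the batch's control measurement units
#' (vial totals for eggs, per-ovary counts for ovarioles).
#'
#' @param measurements data.frame with columns \code{gene}, \code{batch},
#'   \code{x} (one aggregate measurement per gene)
#' @param controls data.frame with columns \code{batch}, \code{value} (one
#'   row per control measurement unit)
#' @return data.frame \code{gene}, \code{batch}, \code{x}, \code{z}
#' @examples
#' m <- data.frame(gene = "g1", batch = "b1", x = 16)
#' ctl <- data.frame(batch = "b1", value = c(8, 10, 12, 10, 10))
#' batchStandardise(m, ctl)  # z ~ 4.24
#' @export
batchStandardise <- function(measurements, controls) {
  stopifnot(all(c("gene", "batch", "x") %in% names(measurements)),
            all(c("batch", "value") %in% names(controls)))
  batches <- unique(as.character(measurements$batch))
  stats <- lapply(batches, function(b) {
    v <- controls$value[as.character(controls$batch) == b]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop("batch '", b, "' has fewer than 2 control measurements")
    s <- stats::sd(v)
    if (s == 0) stop("batch '", b, "' has zero control standard deviation")
    c(mu = mean(v), sigma = s)
  })
  names(stats) <- batches
  mu <- vapply(as.character(measurements$batch), function(b) stats[[b]]["mu"], 0)
  sigma <- vapply(as.character(measurements$batch), function(b) stats[[b]]["sigma"], 0)
  data.frame(gene = as.character(measurements$gene),
             batch = as.character(measurements$batch),
             x = measurements$x,
             z = (measurements$x - mu) / sigma,
             stringsAsFactors = FALSE)
}

#' Z scores for one screen from raw measurement tables
#'
#' Convenience wrapper that aggregates raw records and standardises per
#' batch. For an egg-laying screen, candidate and control measurement units
#' are vial totals (\code{\link{eggTotal}}; vials with a death are
#' excluded, and genes whose only vial is excluded are dropped with a
#' message). For an ovariole screen the candidate measurement is the mean
#' of the gene's ovary counts and control units are the pooled per-ovary
#' counts.
#'
#' @param records data.frame of raw records. Egg schema: \code{gene_id},
#'   \code{batch_id}, \code{vial_id}, \code{day1}..\code{day5},
#'   \code{death_flag}. Ovariole schema: \code{gene_id}, \code{batch_id},
#'   \code{fly_id}, \code{ovary_id}, \code{ovariole_count}.
#' @param type "eggs" or "ovarioles"
#' @param controlLabel gene_id value marking control records
#' @return data.frame \code{gene}, \code{batch}, \code{x}, \code{z} (one
#'   row per candidate gene)
#' @export
screenZScores <- function(records, type = c("eggs", "ovarioles"),
                          controlLabel = "CONTROL") {
  type <- match.arg(type)
  gene <- as.character(records$gene_id)
  isCtl <- gene == controlLabel
  if (type == "eggs") {
    daily <- as.matrix(records[, paste0("day", 1:5)])
    death <- as.logical(records$death_flag)
    tot <- vapply(seq_len(nrow(records)),
                  function(i) as.numeric(eggTotal(daily[i, ], death[i])),
                  numeric(1))
    ctl <- data.frame(batch = as.character(records$batch_id)[isCtl],
                      value = tot[isCtl])
    ctl <- ctl[!is.na(ctl$value), , drop = FALSE]
    cand <- data.frame(gene = gene[!isCtl],
                       batch = as.character(records$batch_id)[!isCtl],
                       x = tot[!isCtl], stringsAsFactors = FALSE)
    drop <- is.na(cand$x)
    if (any(drop)) {
      message(sum(drop), " candidate vial(s) excluded (death) and dropped ",
              "from the screen table")
      cand <- cand[!drop, , drop = FALSE]
    }
  } else {
    cnt <- as.numeric(records$ovariole_count)
    ctl <- data.frame(batch = as.character(records$batch_id)[isCtl],
                      value = cnt[isCtl])
    candRec <- data.frame(gene = gene[!isCtl],
                          batch = as.character(records$batch_id)[!isCtl],
                          value = cnt[!isCtl], stringsAsFactors = FALSE)
    agg <- stats::aggregate(value ~ gene + batch, data = candRec,
                            FUN = ovarioleAggregate)
    cand <- data.frame(gene = agg$gene, batch = agg$batch, x = agg$value,
                       stringsAsFactors = FALSE)
  }
  batchStandardise(cand, ctl)
}

#' Classify a Z score into a phenotype call
#'
#' Strict inequalities on both sides: \code{negative} iff \eqn{z < -T},
#' \code{positive} iff \eqn{z > T}, otherwise \code{none} (a score exactly
#' at the threshold is \code{none}).
#'
#' @param z numeric vector of Z scores
#' @param threshold positive threshold T
#' @return character vector in \{"negative", "none", "positive"\}
#' @examples
#' classifyPhenotype(c(-5.2, 5, 2.1), 5)  # negative, none, none
#' @export
classifyPhenotype <- function(z, threshold) {
  stopifnot(threshold > 0)
  ifelse(z < -threshold, "negative", ifelse(z > threshold, "positive", "none"))
}

#' Primary-screen filter on the sensitised egg-laying Z score
#'
#' Only genes whose primary-screen egg-laying |Z| exceeds 1 proceed to the
#' secondary screens; a |Z| of exactly 1 is dropped.
#'
#' @param z numeric vector of primary-screen Z scores
#' @return logical: retain the gene?
#' @examples
#' primaryFilter(c(0.5, -1.3, 1))  # FALSE TRUE FALSE
#' @export
primaryFilter <- function(z) abs(z) > 1

#' Build the four seed lists from per-screen phenotype calls
#'
#' Genes called (non-\code{none}) in a screen form that screen's seed list;
#' the core list holds genes called in all three screens.
#'
#' @param calls data.frame with columns \code{screen} (one of
#'   "hpo_egg_laying", "egg_laying", "hpo_ovariole"), \code{gene},
#'   \code{call}
#' @return named list of four character vectors: \code{hpo_egg_laying},
#'   \code{egg_laying}, \code{hpo_ovariole}, \code{core}
#' @export
buildSeedLists <- function(calls) {
  screens <- c("hpo_egg_laying", "egg_laying", "hpo_ovariole")
  perScreen <- lapply(screens, function(s) {
    sub <- calls[calls$screen == s, , drop = FALSE]
    sort(unique(as.character(sub$gene[sub$call != "none"])))
  })
  names(perScreen) <- screens
  core <- Reduce(intersect, perScreen)
  c(perScreen, list(core = core))
}

#' Correlation between two per-gene phenotype measures
#'
#' Pairs in which either value is zero are removed before computing the
#' correlation (mirroring a comparison of non-zero ovariole-number and
#' egg-laying values); missing pairs are also dropped. The p-value is the
#' two-sided test from \code{stats::cor.test}, or a label-permutation
#' p-value when \code{permutations > 0}.
#'
#' @param x,y numeric vectors of equal length
#' @param method "pearson" (default) or "spearman"
#' @param permutations if positive, number of random permutations of
#'   \code{y} used to compute an empirical two-sided p-value
#' @return list with \code{r}, \code{p} and \code{n} (pairs used)
#' @export
phenotypeCorrelation <- function(x, y, method = c("pearson", "spearman"),
                                 permutations = 0L) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y) & x != 0 & y != 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("fewer than 3 usable non-zero pairs")
  r <- stats::cor(x, y, method = method)
  if (permutations > 0L) {
    null <- replicate(permutations,
                      stats::cor(x, sample(y), method = method))
    p <- (1 + sum(abs(null) >= abs(r))) / (permutations + 1)
  } else {
    p <- stats::cor.test(x, y, method = method, exact = FALSE)$p.value
  }
  list(r = r, p = p, n = length(x))
}

#' Compare hit strength between extreme centrality quintiles
#'
#' Ranks genes by a centrality measure, forms quintiles (quintile 1 =
#' lowest centrality; ties broken by gene identifier), and compares the
#' |Z| magnitudes of the first and fifth quintiles with a two-sided
#' Wilcoxon rank-sum test. Asks whether central genes show stronger
#' phenotypes, not merely more frequent ones.
#'
#' @param centrality numeric per-gene centrality values
#' @param zMagnitude numeric per-gene |Z| values (same order)
#' @param genes character gene identifiers (same order), used for
#'   deterministic tie-breaking
#' @return list with \code{statistic} (rank-sum W), \code{p},
#'   \code{median_q1}, \code{median_q5}, \code{n_q1}, \code{n_q5}
#' @export
quintileStrengthTest <- function(centrality, zMagnitude, genes = NULL) {
  n <- length(centrality)
  stopifnot(length(zMagnitude) == n)
  if (n < 10L) stop("at least 10 genes are needed to form quintiles")
  if (is.null(genes)) genes <- sprintf("g%06d", seq_len(n))
  o <- order(centrality, genes)
  q <- cut(seq_len(n), breaks = 5, labels = FALSE)
  z1 <- zMagnitude[o][q == 1]
  z5 <- zMagnitude[o][q == 5]
  if (!length(z1) || !length(z5)) stop("empty quintile")
  if (length(unique(c(z1, z5))) == 1L) {
    # all magnitudes tied: no evidence of a difference
    wt <- list(statistic = c(W = length(z1) * length(z5) / 2), p.value = 1)
  } else {
    wt <- stats::wilcox.test(z5, z1, exact = FALSE, correct = FALSE)
  }
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_q1 = stats::median(z1), median_q5 = stats::median(z5),
       n_q1 = length(z1), n_q5 = length(z5))
}
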