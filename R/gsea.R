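# Preranked gene set enrichment analysis from scratch: weighted
# Kolmogorov-Smirnov running sum, gene-label permutation null, NES, and a
# multi-signature / multi-dataset benchmarking harness.

#' Rank genes by a two-group test statistic
#'
#' Builds the preranked list for GSEA: the per-gene Welch t-statistic of
#' condition A vs condition B, sorted descending with ties broken
#' lexicographically by gene identifier. The metric equals the `t` column
#' of [differentialExpression()] for the same contrast.
#'
#' @param se `SummarizedExperiment` with assay `log2` and colData
#'   `condition` (and `model` when subsetting).
#' @param conditions length-2 character `(A, B)`; positive metrics mean
#'   higher in A.
#' @param model optional model label to subset samples first.
#' @return data.frame `gene`, `metric`, sorted descending.
#' @export
rankGenes <- function(se, conditions = c("senescent", "EP"), model = NULL) {
  cd <- SummarizedExperiment::colData(se)
  keep <- cd$condition %in% conditions
  if (!is.null(model)) keep <- keep & cd$model == model
  if (!any(keep)) stop("no samples for the requested contrast")
  x <- SummarizedExperiment::assay(se, "log2")[, keep, drop = FALSE]
  cond <- cd$condition[keep]
  a <- x[, cond == conditions[1L], drop = FALSE]
  b <- x[, cond == conditions[2L], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    stop("insufficient replication: need >= 2 samples per condition")
  }
  tt <- rowTTest(a, b)
  ord <- order(-tt$t, rownames(x))
  data.frame(gene = rownames(x)[ord], metric = tt$t[ord], row.names = NULL)
}

# ES at candidate extremum positions given hit indices; reproduces the
# full running-sum scan (first position on |value| ties) in O(k).
esFromHits <- function(w, N, hitIdx) {
  k <- length(hitIdx)
  nr <- sum(w[hitIdx])
  inc <- if (nr > 0) w[hitIdx] / nr else rep(1 / k, k)
  cw <- cumsum(inc)
  missStep <- 1 / (N - k)
  after <- cw - (hitIdx - seq_len(k)) * missStep        # at hit positions
  before <- cw - inc - (hitIdx - seq_len(k)) * missStep # just before hits
  maxv <- max(after)
  minv <- min(before)
  if (abs(maxv) >= abs(minv)) maxv else minv
}

#' Weighted running-sum enrichment score
#'
#' Classical weighted Kolmogorov-Smirnov statistic: walking down the
#' ranked list, gene-set hits increment the running sum by
#' `|metric|^weightExponent` (normalized so hit increments total 1) and
#' misses decrement it by `1/(N - nHits)`; the ES is the running-sum value
#' of maximal absolute deviation from zero. The leading edge contains the
#' set members at or before (positive ES) / at or after (negative ES) the
#' extremum.
#'
#' @param ranked data.frame `gene`, `metric` from [rankGenes()] (sorted
#'   descending).
#' @param geneSet character vector of gene identifiers; its intersection
#'   with the ranked list must be non-empty and proper.
#' @param weightExponent 1 for the classical weighted statistic, 0 for the
#'   unweighted KS variant.
#' @return list with `es`, `runningSum` (length N), `hitIndices`, and
#'   `leadingEdge`.
#' @examples
#' rl <- data.frame(gene = paste0("g", 1:6), metric = c(3, 2, 1, -1, -2, -3))
#' enrichmentScore(rl, c("g1", "g4"))$es  # 0.75
#' @export
enrichmentScore <- function(ranked, geneSet, weightExponent = 1) {
  N <- nrow(ranked)
  hits <- ranked$gene %in% geneSet
  k <- sum(hits)
  if (k == 0L) stop("gene set has no genes in the ranked list")
  if (k == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked$metric)^weightExponent
  nr <- sum(w[hits])
  inc <- numeric(N)
  inc[hits] <- if (nr > 0) w[hits] / nr else 1 / k
  inc[!hits] <- -1 / (N - k)
  running <- cumsum(inc)
  maxv <- max(running); minv <- min(running)
  # extremum of maximal absolute deviation; positive deviation preferred
  # on exact magnitude ties
  es <- if (abs(maxv) >= abs(minv)) maxv else minv
  iext <- if (es == maxv) which.max(running) else which.min(running)
  hitIdx <- which(hits)
  leading <- if (es > 0) {
    ranked$gene[hitIdx[hitIdx <= iext]]
  } else if (es < 0) {
    ranked$gene[hitIdx[hitIdx >= iext]]
  } else {
    character()
  }
  list(es = es, runningSum = running, hitIndices = hitIdx,
       leadingEdge = leading)
}

#' Permutation-normalized enrichment
#'
#' Builds a null distribution of enrichment scores from `nPerm` random
#' gene-label sets of the same size drawn without replacement from the
#' ranked universe. `NES = ES / mean(|null ES|)` restricted to nulls of
#' the same sign as the observed ES; the permutation p-value is
#' `(1 + #same-sign nulls with |null| >= |ES|) / (1 + #same-sign nulls)`.
#' Gene-label (rather than phenotype) permutation is used because the
#' benchmarked datasets may have as few as three samples per arm.
#' Deterministic for a fixed seed.
#'
#' @inheritParams enrichmentScore
#' @param nPerm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param signatureName label stored in the result.
#' @return An [EnrichmentResult-class].
#' @export
normalizedEnrichment <- function(ranked, geneSet, nPerm = 1000, seed = 1L,
                                 weightExponent = 1,
                                 signatureName = "geneset") {
  stopifnot(nPerm >= 100)
  obs <- enrichmentScore(ranked, geneSet, weightExponent)
  N <- nrow(ranked)
  k <- length(obs$hitIndices)
  w <- abs(ranked$metric)^weightExponent
  set.seed(as.integer(seed))
  null <- vapply(seq_len(nPerm), function(i) {
    esFromHits(w, N, sort(sample.int(N, k)))
  }, numeric(1))
  if (obs$es == 0) {
    nes <- 0
    p <- 1
  } else {
    same <- sign(null) == sign(obs$es)
    if (!any(same)) {
      warning("no same-sign null enrichment scores; NES undefined")
      nes <- NA_real_
      p <- 1 / (1 + 0)
    } else {
      nes <- obs$es / mean(abs(null[same]))
      p <- (1 + sum(abs(null[same]) >= abs(obs$es))) / (1 + sum(same))
    }
  }
  new("EnrichmentResult", signatureName = signatureName, es = obs$es,
      nes = nes, pPerm = p, nPerm = as.integer(nPerm),
      leadingEdge = obs$leadingEdge, seed = as.integer(seed))
}

#' Benchmark signatures across datasets
#'
#' Scores every signature direction (up-set and, when present, down-set)
#' on the preranked list of every dataset, mirroring an NES grid of
#' signatures x datasets. Each cell uses a seed deterministically derived
#' from `seed` and the cell's labels, so individual cells can be
#' reproduced in isolation.
#'
#' @param signatures list of [GeneSignature-class] objects.
#' @param datasets named list; each element is a list with `se` (a
#'   `SummarizedExperiment`) and `conditions` (length-2 contrast for
#'   [rankGenes()]), plus optional `model`.
#' @param nPerm permutations per cell.
#' @param seed base seed.
#' @param weightExponent passed to [enrichmentScore()].
#' @return data.frame with one row per (signature, direction, dataset):
#'   `signature`, `direction`, `dataset`, `size`, `es`, `nes`, `pPerm`,
#'   `nLeadingEdge`. Cells whose gene set has no overlap with the dataset
#'   are reported as NA with a message.
#' @export
benchmarkSignatures <- function(signatures, datasets, nPerm = 1000,
                                seed = 1L, weightExponent = 1) {
  stopifnot(length(signatures) >= 1L, length(datasets) >= 1L,
            !is.null(names(datasets)))
  rows <- list()
  for (dname in names(datasets)) {
    d <- datasets[[dname]]
    ranked <- rankGenes(d$se, conditions = d$conditions, model = d$model)
    for (sig in signatures) {
      dirSets <- list(up = upGenes(sig), down = downGenes(sig))
      for (dir in names(dirSets)) {
        gs <- dirSets[[dir]]
        if (length(gs) == 0L) next
        label <- paste0(sigName(sig), "_", dir)
        if (!any(ranked$gene %in% gs)) {
          message("signature '", label, "' has no genes in dataset '",
                  dname, "'; cell skipped")
          rows[[length(rows) + 1L]] <- data.frame(
            signature = sigName(sig), direction = dir, dataset = dname,
            size = 0L, es = NA_real_, nes = NA_real_, pPerm = NA_real_,
            nLeadingEdge = NA_integer_)
          next
        }
        cellSeed <- stageSeed(seed, paste(dname, label, sep = "/"))
        er <- normalizedEnrichment(ranked, gs, nPerm = nPerm,
                                   seed = cellSeed,
                                   weightExponent = weightExponent,
                                   signatureName = label)
        rows[[length(rows) + 1L]] <- data.frame(
          signature = sigName(sig), direction = dir, dataset = dname,
          size = sum(ranked$gene %in% gs), es = er@es, nes = er@nes,
          pPerm = er@pPerm, nLeadingEdge = length(er@leadingEdge))
      }
    }
  }
  do.call(rbind, rows)
}

#' Interferon signature metric (ISM) per sample
#'
#' Summarizes the activity of an interferon-stimulated-gene panel per
#' sample: every panel gene is z-scored against the mean and SD of the
#' reference-condition samples, and the ISM of a sample is the median of
#' its panel z-scores. This median-of-z-scores definition is a documented
#' stand-in for the original published metric, whose exact normalization
#' is not restated here.
#'
#' @param se `SummarizedExperiment` with assay `log2` and colData
#'   `condition`.
#' @param isgPanel character vector of panel genes (must overlap the
#'   rownames; genes with zero reference SD are dropped with a warning).
#' @param referenceCondition condition defining the reference mean/SD
#'   (needs >= 2 samples).
#' @return named numeric vector: one score per sample.
#' @export
ismScore <- function(se, isgPanel, referenceCondition = "EP") {
  cd <- SummarizedExperiment::colData(se)
  ref <- cd$condition == referenceCondition
  if (sum(ref) < 2L) stop("reference condition needs >= 2 samples")
  x <- SummarizedExperiment::assay(se, "log2")
  panel <- intersect(isgPanel, rownames(x))
  if (length(panel) == 0L) stop("no panel genes present in the dataset")
  xr <- x[panel, ref, drop = FALSE]
  m <- rowMeans(xr)
  s <- sqrt(rowSums((xr - m)^2) / (ncol(xr) - 1))
  drop <- s == 0
  if (any(drop)) {
    warning(sum(drop), " panel gene(s) with zero reference SD dropped")
    panel <- panel[!drop]
    if (length(panel) == 0L) stop("all panel genes degenerate")
    m <- m[!drop]; s <- s[!drop]
  }
  z <- (x[panel, , drop = FALSE] - m) / s
  apply(z, 2L, median)
}
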