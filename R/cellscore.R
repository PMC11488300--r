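# Single-cell QC filtering, normalization, rank-based signature scoring,
# score correlation, mixture-model senescence annotation, and group
# comparison.

#' QC thresholds for barcode filtering
#'
#' Cells are retained only when `minGenes < detectedGenes < maxGenes` and
#' `minMito < mitoFraction < maxMito` (strict comparisons: a cell exactly
#' at a boundary is kept). Presets quote published barcode filters:
#' `"mouse-retina"` excludes barcodes expressing fewer than 500 or more
#' than 6000 genes, or with more than 20% / less than 1% mitochondrial
#' reads; `"human-ecfc"` uses 2000/9000 genes and 1%/10% mitochondrial
#' reads; `"synthetic-lifespan"` is the window the bundled single-cell
#' simulator plants its violators against (100/1950 genes, 1%/10% at the
#' default 2000-gene universe).
#'
#' @param minGenes,maxGenes detected-gene window (counts).
#' @param minMito,maxMito mitochondrial-fraction window in \[0, 1\].
#' @return list of class `QCThresholds`.
#' @export
qcThresholds <- function(minGenes, maxGenes, minMito, maxMito) {
  thr <- list(minGenes = as.numeric(minGenes),
              maxGenes = as.numeric(maxGenes),
              minMito = as.numeric(minMito), maxMito = as.numeric(maxMito))
  if (!(thr$minGenes < thr$maxGenes)) stop("minGenes must be < maxGenes")
  if (!(thr$minMito < thr$maxMito)) stop("minMito must be < maxMito")
  class(thr) <- "QCThresholds"
  thr
}

#' @rdname qcThresholds
#' @param name preset name: `"mouse-retina"`, `"human-ecfc"`, or
#'   `"synthetic-lifespan"`.
#' @param nGenes gene-universe size used to scale the synthetic preset.
#' @export
qcPreset <- function(name = c("mouse-retina", "human-ecfc",
                              "synthetic-lifespan"),
                     nGenes = 2000) {
  name <- match.arg(name)
  switch(name,
    "mouse-retina" = qcThresholds(500, 6000, 0.01, 0.20),
    "human-ecfc" = qcThresholds(2000, 9000, 0.01, 0.10),
    "synthetic-lifespan" = {
      w <- syntheticQcWindow(nGenes)
      qcThresholds(w$minGenes, w$maxGenes, w$minMito, w$maxMito)
    })
}

#' Filter barcodes on detected genes and mitochondrial fraction
#'
#' Removes cells whose detected-gene count or mitochondrial fraction falls
#' outside the open threshold window. A cell failing several criteria is
#' removed once and attributed to the first failing criterion in the order
#' genes-low, genes-high, mito-high, mito-low.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay and colData
#'   column `mitoFraction`. `detectedGenes` is taken from colData when
#'   present, otherwise recomputed as the per-cell number of nonzero
#'   genes.
#' @param thr a [qcThresholds()] object.
#' @return list with `sce` (filtered) and `report` (list: `nInput`,
#'   `removed` named counts per criterion, `nRetained`, `thresholds`).
#' @export
qcFilter <- function(sce, thr) {
  stopifnot(inherits(thr, "QCThresholds"))
  cd <- SummarizedExperiment::colData(sce)
  det <- if ("detectedGenes" %in% names(cd)) {
    as.numeric(cd$detectedGenes)
  } else {
    Matrix::colSums(SummarizedExperiment::assay(sce, "counts") > 0)
  }
  mito <- as.numeric(cd$mitoFraction)
  fail <- cbind(`genes-low` = det < thr$minGenes,
                `genes-high` = det > thr$maxGenes,
                `mito-high` = mito > thr$maxMito,
                `mito-low` = mito < thr$minMito)
  firstFail <- apply(fail, 1L, function(f) {
    w <- which(f)
    if (length(w)) colnames(fail)[w[1L]] else NA_character_
  })
  removed <- table(factor(firstFail, levels = colnames(fail)))
  keep <- is.na(firstFail)
  if (!any(keep)) warning("QC filter removed every cell")
  report <- list(nInput = ncol(sce),
                 removed = setNames(as.integer(removed), names(removed)),
                 nRetained = sum(keep),
                 thresholds = unclass(thr))
  list(sce = sce[, keep], report = report)
}

#' Depth-normalize and log-transform counts
#'
#' Scales every cell to a common target sum and applies `log1p`, writing
#' the result to the `logcounts` assay. Cells with zero total counts are
#' dropped with a warning. Deterministic; sparsity is preserved.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param targetSum common per-cell total after scaling.
#' @return the `SingleCellExperiment` with a `logcounts` assay added.
#' @export
normalizeLog <- function(sce, targetSum = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-count cell(s) dropped")
    sce <- sce[, tot > 0]
    counts <- SummarizedExperiment::assay(sce, "counts")
    tot <- tot[tot > 0]
  }
  norm <- counts %*% Matrix::Diagonal(x = targetSum / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

#' Rank-based per-cell signature score
#'
#' Scores each cell for a gene signature with a clipped Mann-Whitney
#' U-statistic on expression ranks: genes are ranked per cell by
#' normalized expression, descending, with average ranks for ties (so
#' all-zero genes share the bottom ranks); ranks are clipped at
#' `rMax + 1`; then
#' `U' = sum(clipped ranks of the set) - n(n+1)/2` and
#' `score = 1 - U' / (n * rMax)`, which lies in \[0, 1\] and equals 1 when
#' the set occupies the top ranks. For signatures with a down-set the
#' score is `score(up) - score(down)`. Being rank-based, the score is
#' invariant to any monotone transformation of a cell's expression
#' profile. Deterministic.
#'
#' @param sce `SingleCellExperiment`; a `logcounts` assay is used and
#'   computed via [normalizeLog()] if absent.
#' @param sig a [GeneSignature-class]; at least one signature gene must be
#'   present in the dataset.
#' @param rMax rank clipping depth: genes ranked beyond `rMax` contribute
#'   as if at rank `rMax + 1`.
#' @return named numeric vector of per-cell scores with attributes
#'   `method` (`"rank-ustat"`), `rMax`, and `signature`.
#' @export
scoreCells <- function(sce, sig, rMax = 1500) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce)) {
    message("no logcounts assay; applying normalizeLog() defaults")
    sce <- normalizeLog(sce)
  }
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  ranks <- apply(x, 2L, function(v) rank(-v, ties.method = "average"))
  setScore <- function(set) {
    present <- intersect(set, rownames(x))
    if (length(present) == 0L) return(NULL)
    n <- length(present)
    clipped <- pmin(ranks[present, , drop = FALSE], rMax + 1)
    u <- colSums(clipped) - n * (n + 1) / 2
    1 - u / (n * rMax)
  }
  up <- setScore(upGenes(sig))
  if (is.null(up)) {
    stop("signature '", sigName(sig), "' has no genes in the dataset")
  }
  score <- up
  if (length(downGenes(sig))) {
    down <- setScore(downGenes(sig))
    if (!is.null(down)) score <- up - down
  }
  names(score) <- colnames(x)
  attr(score, "method") <- "rank-ustat"
  attr(score, "rMax") <- rMax
  attr(score, "signature") <- sigName(sig)
  score
}

#' Pearson correlation between two per-cell score vectors
#'
#' @param a,b numeric score vectors over the same cells (n >= 3; when both
#'   are named the names must match).
#' @return list with `r` (sample Pearson correlation), `p` (two-sided
#'   t-based p-value), and `n`.
#' @export
correlateScores <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("need score vectors of equal length >= 3")
  }
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop("score vectors are over different cells")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop("undefined correlation: a score vector has zero variance")
  }
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

# two-component 1-D Gaussian mixture by EM; k-means init, tol on loglik
fitGmm2 <- function(x, seed, tol = 1e-8, maxIter = 500L) {
  set.seed(as.integer(seed))
  km <- kmeans(x, centers = 2L, nstart = 10L)
  mu <- as.numeric(km$centers)
  sdFloor <- max(sd(x), .Machine$double.eps) * 1e-6
  sigma <- vapply(1:2, function(k) {
    s <- sd(x[km$cluster == k])
    if (!is.finite(s) || s < sdFloor) sdFloor else s
  }, numeric(1))
  weight <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
  ll <- -Inf
  for (iter in seq_len(maxIter)) {
    d1 <- weight[1] * dnorm(x, mu[1], sigma[1])
    d2 <- weight[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d2 / tot
    llNew <- sum(log(tot))
    if (is.finite(llNew) && abs(llNew - ll) < tol) break
    ll <- llNew
    n2 <- sum(g); n1 <- length(x) - n2
    if (min(n1, n2) / length(x) < 1e-3) {
      return(NULL)                       # degenerate component
    }
    mu <- c(sum((1 - g) * x) / n1, sum(g * x) / n2)
    sigma <- c(sqrt(sum((1 - g) * (x - mu[1])^2) / n1),
               sqrt(sum(g * (x - mu[2])^2) / n2))
    sigma[sigma < sdFloor] <- sdFloor
    weight <- c(n1, n2) / length(x)
  }
  if (min(weight) < 1e-3) return(NULL)
  d1 <- weight[1] * dnorm(x, mu[1], sigma[1])
  d2 <- weight[2] * dnorm(x, mu[2], sigma[2])
  tot <- d1 + d2
  tot[tot == 0] <- .Machine$double.xmin
  list(mu = mu, sigma = sigma, weight = weight, posterior2 = d2 / tot)
}

#' Binary senescence annotation from per-cell scores
#'
#' Fits a two-component one-dimensional Gaussian mixture to the score
#' distribution by EM (k-means initialization with the given seed,
#' log-likelihood tolerance 1e-8, at most 500 iterations). The component
#' with the larger mean is labelled senescent; cells are called senescent
#' when their posterior exceeds 0.5. When the mixture degenerates (a
#' component weight below 1e-3, or constant scores) the method falls back
#' to a median split — the upper half of cells is labelled senescent —
#' with a warning. This mixture-model annotation meets the binary
#' senescent / non-senescent contract of published senescence-index
#' tools without reimplementing any of them; the `method` tag records
#' which path produced the call.
#'
#' @param scores numeric per-cell scores (n >= 20).
#' @param groups optional per-cell group labels; when given, per-group
#'   senescent fractions are reported.
#' @param seed RNG seed for the k-means initialization.
#' @return A [SenescenceCall-class].
#' @export
annotateSenescence <- function(scores, groups = NULL, seed = 1L) {
  stopifnot(length(scores) >= 20L)
  if (!is.null(groups)) stopifnot(length(groups) == length(scores))
  fit <- if (sd(scores) == 0) NULL else fitGmm2(scores, seed)
  if (is.null(fit)) {
    warning("degenerate mixture fit; falling back to a median split")
    ord <- order(scores, seq_along(scores))
    upper <- logical(length(scores))
    upper[ord[seq(length(scores) %/% 2 + 1L, length(scores))]] <- TRUE
    post <- as.numeric(upper)
    call <- new("SenescenceCall", posterior = post, label = post > 0.5,
                mu = c(NA_real_, NA_real_), sigma = c(NA_real_, NA_real_),
                weight = c(0.5, 0.5), groupFractions = numeric(),
                method = "median-split")
  } else {
    senComp <- which.max(fit$mu)
    post <- if (senComp == 2L) fit$posterior2 else 1 - fit$posterior2
    ordc <- if (senComp == 2L) 1:2 else 2:1
    call <- new("SenescenceCall", posterior = post, label = post > 0.5,
                mu = fit$mu[ordc], sigma = fit$sigma[ordc],
                weight = fit$weight[ordc], groupFractions = numeric(),
                method = "gmm-em")
  }
  if (!is.null(groups)) {
    frac <- vapply(split(call@label, groups), mean, numeric(1))
    call@groupFractions <- frac[unique(as.character(groups))]
  }
  call
}

#' Compare per-cell scores between groups
#'
#' Per-group mean and median score plus a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test for every group pair, with Benjamini-Hochberg
#' adjustment across pairs. Groups with fewer than 3 cells are excluded
#' with a warning.
#'
#' @param scores numeric per-cell scores.
#' @param groups per-cell group labels.
#' @return list with `summary` (group, n, mean, median) and `tests`
#'   (groupA, groupB, W, p, padj, medianDiff).
#' @export
compareGroups <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("group(s) with < 3 cells excluded: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    scores <- scores[keep]; groups <- groups[keep]
  }
  labs <- unique(groups)
  if (length(labs) < 2L) stop("need >= 2 groups with >= 3 cells")
  summ <- data.frame(
    group = labs,
    n = vapply(labs, function(g) sum(groups == g), integer(1)),
    mean = vapply(labs, function(g) mean(scores[groups == g]), numeric(1)),
    median = vapply(labs, function(g) median(scores[groups == g]),
                    numeric(1)),
    row.names = NULL)
  pairs <- utils::combn(labs, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1L, i]; gb <- pairs[2L, i]
    wt <- suppressWarnings(wilcox.test(scores[groups == ga],
                                       scores[groups == gb]))
    data.frame(groupA = ga, groupB = gb, W = unname(wt$statistic),
               p = wt$p.value,
               medianDiff = median(scores[groups == ga]) -
                 median(scores[groups == gb]))
  }))
  tests$padj <- p.adjust(tests$p, method = "BH")
  list(summary = summ, tests = tests)
}
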