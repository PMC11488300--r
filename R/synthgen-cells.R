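# Synthetic single-cell generator: four-group lifespan design with planted
# signature / SASP program activity, staged senescent fractions, a target
# signature-SASP correlation, and planted QC-violating cells.

#' Configuration for the single-cell lifespan simulator
#'
#' Emulates a replicative-lifespan scRNA-seq experiment with four groups
#' (proliferating early passage, quiescent, mid passage, late passage) whose
#' planted per-group senescent fractions default to 1%, 0%, 29% and 77%.
#' Each cell carries a latent (signature activity, SASP activity) pair; both
#' programs share the senescent mean shift, and independent per-cell noise
#' is calibrated so that the marginal Pearson correlation between the two
#' latent activities across all cells equals `targetSaspCorr` in
#' expectation. Counts are negative binomial over log-normal gene
#' abundances; the mitochondrial fraction is simulated directly as per-cell
#' metadata. QC-violating cells (too few / too many detected genes, too
#' high / too low mitochondrial fraction relative to the generator's QC
#' window) are appended as extra cells and recorded in the truth.
#'
#' @param nGenes number of genes.
#' @param groups data.frame with columns `label`, `nCells`,
#'   `senescentFraction`. The number of senescent cells per group is
#'   `round(nCells * senescentFraction)` (planted exactly).
#' @param signatureShift natural-log fold effect of the senescent state on
#'   planted signature and SASP genes.
#' @param targetSaspCorr target marginal Pearson correlation between the
#'   latent signature and SASP activities; must lie in \[0, 1\] for this
#'   construction.
#' @param nbDispersion negative binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param librarySizeMean mean library size (counts per cell).
#' @param qcViolators integer vector of length 4: planted numbers of
#'   low-gene, high-gene, high-mito and low-mito cells.
#' @param nSignatureGenes,nSaspGenes sizes of the planted signature and
#'   SASP gene sets (disjoint).
#' @param seed integer RNG seed.
#' @return A validated configuration list of class `ScSimConfig`.
#' @export
scSimConfig <- function(nGenes = 2000,
                        groups = data.frame(
                          label = c("EP_prolif", "quiescent", "mid", "late"),
                          nCells = c(700L, 700L, 700L, 700L),
                          senescentFraction = c(0.01, 0.0, 0.29, 0.77)),
                        signatureShift = 1.5,
                        targetSaspCorr = 0.8,
                        nbDispersion = 0.5,
                        librarySizeMean = 10000,
                        qcViolators = c(10L, 10L, 10L, 10L),
                        nSignatureGenes = 75,
                        nSaspGenes = 40,
                        seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), groups = groups,
              signatureShift = as.numeric(signatureShift),
              targetSaspCorr = as.numeric(targetSaspCorr),
              nbDispersion = as.numeric(nbDispersion),
              librarySizeMean = as.numeric(librarySizeMean),
              qcViolators = as.integer(qcViolators),
              nSignatureGenes = as.integer(nSignatureGenes),
              nSaspGenes = as.integer(nSaspGenes),
              seed = as.integer(seed))
  class(cfg) <- "ScSimConfig"
  validateScSimConfig(cfg)
  cfg
}

validateScSimConfig <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid ScSimConfig field '", field, "': ", why, call. = FALSE)
  }
  g <- cfg$groups
  if (!is.data.frame(g) ||
      !all(c("label", "nCells", "senescentFraction") %in% names(g))) {
    fail("groups", "needs columns label, nCells, senescentFraction")
  }
  if (any(g$senescentFraction < 0 | g$senescentFraction > 1)) {
    fail("groups", "senescentFraction must lie in [0, 1]")
  }
  if (any(g$nCells <= 0L)) fail("groups", "nCells must be > 0")
  if (cfg$targetSaspCorr < 0 || cfg$targetSaspCorr > 1) {
    fail("targetSaspCorr",
         "must lie in [0, 1] for the shared-shift construction")
  }
  if (cfg$nbDispersion <= 0) fail("nbDispersion", "must be > 0")
  if (cfg$librarySizeMean <= 0) fail("librarySizeMean", "must be > 0")
  if (length(cfg$qcViolators) != 4L || any(cfg$qcViolators < 0L)) {
    fail("qcViolators", "must be 4 non-negative counts")
  }
  if (cfg$nSignatureGenes + cfg$nSaspGenes > cfg$nGenes) {
    fail("nGenes", "too small for the planted signature + SASP sets")
  }
  if (cfg$nSignatureGenes < 1L || cfg$nSaspGenes < 1L) {
    fail("nSignatureGenes", "planted sets must be non-empty")
  }
  invisible(cfg)
}

# QC window the generator plants its violators against (strict comparisons,
# see qcFilter). Scales with the gene universe; at the default 2000 genes it
# is detected genes in (100, 1950) and mito fraction in (1%, 10%).
syntheticQcWindow <- function(nGenes) {
  list(minGenes = max(2L, as.integer(round(0.05 * nGenes))),
       maxGenes = as.integer(round(0.975 * nGenes)),
       minMito = 0.01, maxMito = 0.10)
}

truncBeta <- function(n, a, b, lo, hi) {
  qbeta(runif(n, pbeta(lo, a, b), pbeta(hi, a, b)), a, b)
}

#' Simulate a staged single-cell senescence dataset
#'
#' See [scSimConfig()] for the generative model. Cells are returned as a
#' [SingleCellExperiment::SingleCellExperiment] with a sparse `counts`
#' assay and colData columns `group`, `detectedGenes` (number of nonzero
#' genes, recomputed from the counts), `mitoFraction`, and `qcViolation`
#' (`"none"` or the planted violation type). Deterministic for a fixed
#' seed.
#'
#' @param config an [scSimConfig()] object.
#' @return A list with elements:
#' \describe{
#'   \item{sce}{the `SingleCellExperiment`.}
#'   \item{truth}{ground-truth list: `signatureGenes`, `saspGenes`,
#'     `senescent` (per-cell logical), `activitySignature`,
#'     `activitySasp` (per-cell latent activities), `groupFractions`
#'     (planted per-group senescent fractions over non-violator cells),
#'     `qcViolators` (barcode + reason), `qcThresholds`,
#'     `targetSaspCorr`.}
#' }
#' @examples
#' sim <- simulateCells(scSimConfig(nGenes = 300, groups = data.frame(
#'   label = c("EP", "late"), nCells = c(50L, 50L),
#'   senescentFraction = c(0, 0.8)), seed = 1))
#' sim$truth$groupFractions
#' @export
simulateCells <- function(config = scSimConfig()) {
  validateScSimConfig(config)
  set.seed(config$seed)
  genes <- geneIds(config$nGenes)
  g <- config$groups

  # planted gene programs, disjoint
  pool <- sample(genes)
  sigGenes <- sort(pool[seq_len(config$nSignatureGenes)])
  saspGenes <- sort(pool[config$nSignatureGenes +
                           seq_len(config$nSaspGenes)])

  nNormal <- sum(g$nCells)
  group <- rep(g$label, g$nCells)
  senescent <- logical(nNormal)
  for (i in seq_len(nrow(g))) {
    idx <- which(group == g$label[i])
    nSen <- round(g$nCells[i] * g$senescentFraction[i])
    if (nSen > 0L) senescent[sample(idx, nSen)] <- TRUE
  }

  # latent program activities: shared senescent shift + calibrated noise so
  # that the marginal correlation across all cells equals targetSaspCorr
  s <- config$signatureShift
  rho <- config$targetSaspCorr
  p <- mean(senescent)
  B <- s^2 * p * (1 - p)
  e1 <- rnorm(nNormal)
  u <- rnorm(nNormal)
  if (B > 0) {
    if (rho > 0) {
      sigma <- s * sqrt(p * (1 - p) * (1 - rho) / rho)
      tau <- 0
    } else {                      # rho == 0: anticorrelated noise cancels B
      sigma <- s * sqrt(p * (1 - p))
      tau <- -1
    }
  } else {                        # no senescent spread: plain bivariate noise
    sigma <- 0.25
    tau <- rho
  }
  e2 <- tau * e1 + sqrt(max(0, 1 - tau^2)) * u
  actSig <- s * senescent + sigma * e1
  actSasp <- s * senescent + sigma * e2

  # counts: log-normal gene abundances, NB noise, log-normal library sizes
  lambda <- rlnorm(config$nGenes, meanlog = log(2), sdlog = 1.2)
  names(lambda) <- genes
  lib <- rlnorm(nNormal, meanlog = log(config$librarySizeMean), sdlog = 0.3)
  sf <- lib / sum(lambda)
  size <- 1 / config$nbDispersion

  mu <- matrix(lambda, nrow = config$nGenes, ncol = nNormal,
               dimnames = list(genes, NULL))
  mu[sigGenes, ] <- mu[sigGenes, ] *
    matrix(exp(actSig), nrow = length(sigGenes), ncol = nNormal, byrow = TRUE)
  mu[saspGenes, ] <- mu[saspGenes, ] *
    matrix(exp(actSasp), nrow = length(saspGenes), ncol = nNormal,
           byrow = TRUE)
  mu <- sweep(mu, 2, sf, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                   nrow = config$nGenes)
  mito <- truncBeta(nNormal, 9, 191, 0.012, 0.098)
  violation <- rep("none", nNormal)

  # planted QC violators, appended as extra cells
  qcw <- syntheticQcWindow(config$nGenes)
  nLow <- max(1L, as.integer(round(qcw$minGenes / 2)))
  nHigh <- min(config$nGenes,
               max(qcw$maxGenes + 1L, as.integer(ceiling(0.995 * config$nGenes))))
  nv <- config$qcViolators
  reasons <- rep(c("genes-low", "genes-high", "mito-high", "mito-low"), nv)
  nViol <- length(reasons)
  if (nViol > 0L) {
    vCounts <- matrix(0L, nrow = config$nGenes, ncol = nViol)
    vMito <- numeric(nViol)
    vGroup <- rep(g$label, length.out = nViol)
    for (k in seq_len(nViol)) {
      base <- rnbinom(config$nGenes, mu = lambda * sf[1L], size = size)
      switch(reasons[k],
        "genes-low" = {
          keep <- sample(config$nGenes, nLow)
          cnt <- integer(config$nGenes)
          cnt[keep] <- pmax(1L, base[keep])
          vCounts[, k] <- cnt
          vMito[k] <- truncBeta(1L, 9, 191, 0.012, 0.098)
        },
        "genes-high" = {
          keep <- sample(config$nGenes, nHigh)
          cnt <- base
          cnt[keep] <- pmax(1L, cnt[keep])
          cnt[-keep] <- 0L
          vCounts[, k] <- cnt
          vMito[k] <- truncBeta(1L, 9, 191, 0.012, 0.098)
        },
        "mito-high" = {
          vCounts[, k] <- base
          vMito[k] <- runif(1L, 0.12, 0.20)
        },
        "mito-low" = {
          vCounts[, k] <- base
          vMito[k] <- runif(1L, 0.001, 0.008)
        })
    }
    counts <- cbind(counts, vCounts)
    mito <- c(mito, vMito)
    group <- c(group, vGroup)
    senescent <- c(senescent, logical(nViol))
    actSig <- c(actSig, numeric(nViol))
    actSasp <- c(actSasp, numeric(nViol))
    violation <- c(violation, reasons)
  }

  barcodes <- sprintf("CELL_%05d", seq_len(ncol(counts)))
  rownames(counts) <- genes
  colnames(counts) <- barcodes
  names(senescent) <- names(actSig) <- names(actSasp) <- barcodes
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(
      group = group,
      detectedGenes = Matrix::colSums(counts > 0),
      mitoFraction = mito,
      qcViolation = violation,
      row.names = barcodes)
  )

  normal <- violation == "none"
  plantedFractions <- vapply(g$label, function(lab) {
    idx <- normal & group == lab
    mean(senescent[idx])
  }, numeric(1))
  truth <- list(
    signatureGenes = sigGenes, saspGenes = saspGenes,
    senescent = senescent,
    activitySignature = actSig, activitySasp = actSasp,
    groupFractions = plantedFractions,
    qcViolators = data.frame(barcode = barcodes[!normal],
                             reason = violation[!normal]),
    qcThresholds = qcw,
    targetSaspCorr = rho, signatureShift = s, seed = config$seed)
  list(sce = sce, truth = truth)
}

#' Simulate a target-driven co-expression module
#'
#' Small expression simulator for exercising the virtual-knockout stage: a
#' driver gene influences a planted module of downstream genes, all other
#' genes are independent noise. Values are on a normalized log scale and
#' can be fed to [buildNetwork()] directly.
#'
#' @param nGenes total genes (driver + module + independent genes).
#' @param nCells number of cells.
#' @param nModule number of module genes driven by the target.
#' @param beta driver-to-module effect size.
#' @param noiseSd residual SD of module genes.
#' @param seed integer RNG seed.
#' @return list with `mat` (genes x cells), `target`, `module`.
#' @export
simulateDriverModule <- function(nGenes = 60, nCells = 300, nModule = 10,
                                 beta = 1.0, noiseSd = 0.3, seed = 1L) {
  stopifnot(nGenes >= nModule + 1L)
  set.seed(as.integer(seed))
  genes <- geneIds(nGenes)
  target <- genes[1L]
  module <- genes[1L + seq_len(nModule)]
  x <- rnorm(nCells)
  mat <- matrix(rnorm(nGenes * nCells), nrow = nGenes,
                dimnames = list(genes, sprintf("CELL_%05d", seq_len(nCells))))
  mat[target, ] <- x
  mat[module, ] <- matrix(rep(beta * x, nModule), nrow = nModule,
                          byrow = TRUE) +
    matrix(rnorm(nModule * nCells, 0, noiseSd), nrow = nModule)
  list(mat = mat, target = target, module = module)
}

#' Write / read a single-cell dataset as a Matrix Market triplet
#'
#' `writeCellDataset()` writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#' and `cellmeta.tsv` (group, detectedGenes, mitoFraction, qcViolation)
#' under `dir`; `readCellDataset()` reads them back.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return `readCellDataset()` returns a `SingleCellExperiment`.
#' @export
writeCellDataset <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  md <- data.frame(barcode = rownames(cd), cd, check.names = FALSE)
  write.table(md, file.path(dir, "cellmeta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCellDataset
#' @export
readCellDataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  metaPath <- file.path(dir, "cellmeta.tsv")
  if (file.exists(metaPath)) {
    md <- read.delim(metaPath, check.names = FALSE)
    stopifnot(identical(md$barcode, colnames(counts)))
    cd <- S4Vectors::DataFrame(md[, setdiff(names(md), "barcode"),
                                  drop = FALSE],
                               row.names = md$barcode)
  } else {
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
}
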