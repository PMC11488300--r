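# Synthetic bulk expression generator: multi-donor, multi-model senescence
# design with a planted shared up/down program, model-specific DE, and an
# optional interferon-treated arm sharing part of the up program.

#' Configuration for the bulk expression simulator
#'
#' Defines the planted structure of a synthetic multi-model senescence
#' experiment: three induction models by default, paired early-passage (EP)
#' and senescent arms with a shared random donor intercept, a shared
#' up/down program of 75/209 genes, 300 model-specific genes per model
#' (half up, half down), and an optional interferon-treated arm whose
#' planted response overlaps the shared program in 19 up and 8 down genes.
#'
#' Values are continuous log2 intensities (microarray-like), not counts.
#'
#' @param nGenes total number of genes.
#' @param nDonors number of donors; each donor contributes one sample per
#'   model x condition.
#' @param models character vector of senescence-induction model labels.
#' @param nSharedUp,nSharedDown sizes of the planted shared up/down program.
#' @param nModelSpecific number of model-specific DE genes per model
#'   (split evenly between up and down).
#' @param effectLog2fc planted effect size, log2 units.
#' @param residualSd per-sample residual SD, log2 units.
#' @param donorSd SD of the shared per-donor random intercept, log2 units.
#' @param ifnArm logical; add an interferon-treated arm (conditions "IFN"
#'   plus its own "EP" controls under model label "ifn").
#' @param nIfnOverlapUp,nIfnOverlapDown number of shared program genes that
#'   also respond to interferon (subsets of the shared up/down sets).
#' @param seed integer RNG seed; fixing it fixes every output byte.
#' @return A validated configuration list of class `BulkSimConfig`.
#' @examples
#' cfg <- bulkSimConfig(nGenes = 500, nSharedUp = 20, nSharedDown = 20,
#'                      nModelSpecific = 30, nIfnOverlapUp = 5,
#'                      nIfnOverlapDown = 3, seed = 1)
#' sim <- simulateBulk(cfg)
#' dim(SummarizedExperiment::assay(sim$se))
#' @export
bulkSimConfig <- function(nGenes = 5000,
                          nDonors = 3,
                          models = c("replicative", "xray", "etoposide"),
                          nSharedUp = 75,
                          nSharedDown = 209,
                          nModelSpecific = 300,
                          effectLog2fc = 2.0,
                          residualSd = 0.5,
                          donorSd = 0.3,
                          ifnArm = TRUE,
                          nIfnOverlapUp = 19,
                          nIfnOverlapDown = 8,
                          seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nDonors = as.integer(nDonors),
              models = as.character(models),
              nSharedUp = as.integer(nSharedUp),
              nSharedDown = as.integer(nSharedDown),
              nModelSpecific = as.integer(nModelSpecific),
              effectLog2fc = as.numeric(effectLog2fc),
              residualSd = as.numeric(residualSd),
              donorSd = as.numeric(donorSd),
              ifnArm = isTRUE(ifnArm),
              nIfnOverlapUp = as.integer(nIfnOverlapUp),
              nIfnOverlapDown = as.integer(nIfnOverlapDown),
              seed = as.integer(seed))
  class(cfg) <- "BulkSimConfig"
  validateBulkSimConfig(cfg)
  cfg
}

validateBulkSimConfig <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid BulkSimConfig field '", field, "': ", why, call. = FALSE)
  }
  counts <- c(nGenes = cfg$nGenes, nDonors = cfg$nDonors,
              nSharedUp = cfg$nSharedUp, nSharedDown = cfg$nSharedDown,
              nModelSpecific = cfg$nModelSpecific)
  for (f in names(counts)) {
    if (is.na(counts[[f]]) || counts[[f]] <= 0L) fail(f, "must be > 0")
  }
  if (length(cfg$models) < 1L) fail("models", "needs at least one model")
  if (anyDuplicated(cfg$models)) fail("models", "labels must be unique")
  planted <- cfg$nSharedUp + cfg$nSharedDown +
    length(cfg$models) * cfg$nModelSpecific
  if (planted > cfg$nGenes) {
    fail("nGenes", sprintf("planted sets need %d genes but nGenes = %d",
                           planted, cfg$nGenes))
  }
  if (cfg$nIfnOverlapUp > cfg$nSharedUp) {
    fail("nIfnOverlapUp", "cannot exceed nSharedUp")
  }
  if (cfg$nIfnOverlapDown > cfg$nSharedDown) {
    fail("nIfnOverlapDown", "cannot exceed nSharedDown")
  }
  if (cfg$residualSd < 0) fail("residualSd", "must be >= 0")
  if (cfg$donorSd < 0) fail("donorSd", "must be >= 0")
  invisible(cfg)
}

geneIds <- function(n) sprintf("G%06d", seq_len(n))

#' Simulate a multi-model bulk senescence experiment
#'
#' Draws one log2-scale expression sample per donor x model x condition
#' (plus an interferon arm when enabled). Baseline log2 means are drawn
#' once per gene; senescent samples of every model are shifted by
#' `+effectLog2fc` on the shared up program and `-effectLog2fc` on the
#' shared down program; model-specific genes are shifted only in their
#' model; the interferon arm shifts only the planted overlap genes. Every
#' sample receives its donor's shared random intercept plus independent
#' residual noise. Deterministic for a fixed seed.
#'
#' @param config a [bulkSimConfig()] object.
#' @return A list with elements:
#' \describe{
#'   \item{se}{[SummarizedExperiment::SummarizedExperiment] with assay
#'     `log2` (genes x samples) and colData columns `donor`, `model`,
#'     `condition` (`EP`, `senescent`, or `IFN`).}
#'   \item{truth}{ground-truth list: `sharedUp`, `sharedDown`,
#'     `modelSpecific` (per model, `$up`/`$down`), `ifnUp`, `ifnDown`,
#'     `effectLog2fc`.}
#' }
#' @examples
#' sim <- simulateBulk(bulkSimConfig(nGenes = 400, nSharedUp = 15,
#'                                   nSharedDown = 20, nModelSpecific = 20,
#'                                   nIfnOverlapUp = 5, nIfnOverlapDown = 3,
#'                                   seed = 3))
#' table(SummarizedExperiment::colData(sim$se)$condition)
#' @export
simulateBulk <- function(config = bulkSimConfig()) {
  validateBulkSimConfig(config)
  set.seed(config$seed)
  genes <- geneIds(config$nGenes)

  # planted sets drawn without replacement, mutually disjoint
  pool <- sample(genes)
  takeFrom <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  sharedUp <- sort(takeFrom(config$nSharedUp))
  sharedDown <- sort(takeFrom(config$nSharedDown))
  nSpecUp <- config$nModelSpecific %/% 2L
  modelSpecific <- lapply(config$models, function(m) {
    list(up = sort(takeFrom(nSpecUp)),
         down = sort(takeFrom(config$nModelSpecific - nSpecUp)))
  })
  names(modelSpecific) <- config$models
  ifnUp <- sort(sample(sharedUp, config$nIfnOverlapUp))
  ifnDown <- sort(sample(sharedDown, config$nIfnOverlapDown))

  baseline <- rnorm(config$nGenes, mean = 7, sd = 1.5)
  names(baseline) <- genes
  donors <- sprintf("D%d", seq_len(config$nDonors))
  donorEffect <- setNames(rnorm(config$nDonors, 0, config$donorSd), donors)

  arms <- list()
  for (m in config$models) {
    for (cond in c("EP", "senescent")) {
      arms[[length(arms) + 1L]] <- data.frame(model = m, condition = cond,
                                              donor = donors)
    }
  }
  if (config$ifnArm) {
    for (cond in c("EP", "IFN")) {
      arms[[length(arms) + 1L]] <- data.frame(model = "ifn", condition = cond,
                                              donor = donors)
    }
  }
  meta <- do.call(rbind, arms)
  meta$sample <- sprintf("%s_%s_%s", meta$model, meta$condition, meta$donor)
  rownames(meta) <- meta$sample

  eff <- config$effectLog2fc
  values <- matrix(0, nrow = config$nGenes, ncol = nrow(meta),
                   dimnames = list(genes, meta$sample))
  for (j in seq_len(nrow(meta))) {
    mu <- baseline
    if (meta$condition[j] == "senescent") {
      mu[sharedUp] <- mu[sharedUp] + eff
      mu[sharedDown] <- mu[sharedDown] - eff
      spec <- modelSpecific[[meta$model[j]]]
      mu[spec$up] <- mu[spec$up] + eff
      mu[spec$down] <- mu[spec$down] - eff
    } else if (meta$condition[j] == "IFN") {
      mu[ifnUp] <- mu[ifnUp] + eff
      mu[ifnDown] <- mu[ifnDown] - eff
    }
    values[, j] <- mu + donorEffect[[meta$donor[j]]] +
      rnorm(config$nGenes, 0, config$residualSd)
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(meta[, c("donor", "model", "condition")],
                                   row.names = meta$sample)
  )
  truth <- list(sharedUp = sharedUp, sharedDown = sharedDown,
                modelSpecific = modelSpecific,
                ifnUp = ifnUp, ifnDown = ifnDown,
                effectLog2fc = eff, seed = config$seed)
  list(se = se, truth = truth)
}

#' Write / read a bulk expression dataset as TSV
#'
#' `writeBulkExpression()` writes `<prefix>_expression.tsv` (genes x
#' samples, first column `gene`) and `<prefix>_samples.tsv` (sample,
#' donor, model, condition). `readBulkExpression()` reads them back into a
#' `SummarizedExperiment`.
#'
#' @param se a `SummarizedExperiment` with assay `log2` and colData
#'   `donor`, `model`, `condition`.
#' @param prefix path prefix for the two TSV files.
#' @return `writeBulkExpression()` the two file paths, invisibly;
#'   `readBulkExpression()` a `SummarizedExperiment`.
#' @export
writeBulkExpression <- function(se, prefix) {
  exprPath <- paste0(prefix, "_expression.tsv")
  metaPath <- paste0(prefix, "_samples.tsv")
  x <- SummarizedExperiment::assay(se, "log2")
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(df, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  md <- data.frame(sample = rownames(cd), cd, check.names = FALSE)
  write.table(md, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = exprPath, samples = metaPath))
}

#' @rdname writeBulkExpression
#' @export
readBulkExpression <- function(prefix) {
  x <- read.delim(paste0(prefix, "_expression.tsv"), check.names = FALSE)
  md <- read.delim(paste0(prefix, "_samples.tsv"), check.names = FALSE)
  mat <- as.matrix(x[, -1, drop = FALSE])
  rownames(mat) <- x$gene
  stopifnot(identical(colnames(mat), md$sample))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat),
    colData = S4Vectors::DataFrame(md[, setdiff(names(md), "sample"),
                                      drop = FALSE],
                                   row.names = md$sample)
  )
}

#' Write / read a ground-truth list as JSON
#'
#' @param truth ground-truth list from [simulateBulk()] or
#'   [simulateCells()].
#' @param path JSON file path.
#' @return `readGroundTruth()` returns the list.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
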