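# Reproducible multi-stage pipeline: simulate -> derive -> benchmark ->
# score-cells -> knockout -> rip -> report. Every stage writes a manifest
# (parameters, seed, package version, content hashes); rerunning with an
# identical configuration reproduces identical bytes.

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters. A YAML file loaded with
#' [loadRunConfig()] may override any subset; unknown keys are rejected.
#' The global `seed` deterministically derives per-stage seeds via
#' [stageSeed()].
#'
#' @return nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    outputDir = "senesig-run",
    seed = 1L,
    simulate = list(
      bulk = list(nGenes = 5000L, nDonors = 3L,
                  models = c("replicative", "xray", "etoposide"),
                  nSharedUp = 75L, nSharedDown = 209L,
                  nModelSpecific = 300L, effectLog2fc = 2.0,
                  residualSd = 0.5, donorSd = 0.3, ifnArm = TRUE,
                  nIfnOverlapUp = 19L, nIfnOverlapDown = 8L),
      cells = list(nGenes = 2000L, nCellsPerGroup = 700L,
                   signatureShift = 1.5, targetSaspCorr = 0.8,
                   nbDispersion = 0.5, librarySizeMean = 10000,
                   qcViolators = c(10L, 10L, 10L, 10L),
                   nSignatureGenes = 75L, nSaspGenes = 40L)
    ),
    derive = list(name = "consensus", fcThreshold = 1.0, pThreshold = 0.05,
                  paired = FALSE, topN = 20L),
    benchmark = list(nPerm = 1000L, nDecoys = 1L, signatureFiles = list()),
    scoreCells = list(qcPreset = "synthetic-lifespan", rMax = 1500L,
                      targetSum = 10000),
    knockout = list(target = NULL, nGenes = 200L, nPcs = 5L, ridge = 1.0,
                    sparsityQuantile = 0.95, alpha = 0.5, horizon = 3L,
                    topN = 50L),
    rip = list(input = NULL, dilutionFactor = 100)
  )
}

mergeConfig <- function(default, override, path = character()) {
  for (key in names(override)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(default)) {
      stop("unknown configuration key '", here, "'")
    }
    if (is.list(default[[key]]) && !is.data.frame(default[[key]]) &&
        is.list(override[[key]])) {
      default[[key]] <- mergeConfig(default[[key]], override[[key]],
                                    c(path, key))
    } else {
      default[[key]] <- override[[key]]
    }
  }
  default
}

#' Load a pipeline configuration
#'
#' Merges (in order of increasing precedence) the defaults, a YAML file,
#' and a list of programmatic overrides. Unknown keys raise an error
#' naming the offending key path.
#'
#' @param path optional YAML file.
#' @param overrides optional nested list of overrides.
#' @return validated configuration list.
#' @export
loadRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  mergeConfig(cfg, overrides)
}

pipePaths <- function(cfg) {
  d <- cfg$outputDir
  list(dir = d,
       bulkPrefix = file.path(d, "bulk"),
       bulkTruth = file.path(d, "bulk_truth.json"),
       cellsDir = file.path(d, "cells"),
       cellsTruth = file.path(d, "cells_truth.json"),
       dePrefix = file.path(d, "de"),
       gmt = file.path(d, "signature.gmt"),
       euler = file.path(d, "euler_counts.json"),
       topGenes = file.path(d, "top_genes.csv"),
       benchmark = file.path(d, "benchmark.csv"),
       qcReport = file.path(d, "qc_report.json"),
       scores = file.path(d, "cell_scores.csv"),
       calls = file.path(d, "cell_calls.csv"),
       fractions = file.path(d, "group_fractions.csv"),
       scoreStats = file.path(d, "score_stats.json"),
       network = file.path(d, "network.csv"),
       profile = file.path(d, "knockout_profile.csv"),
       koGenes = file.path(d, "knockout_top_genes.txt"),
       ripTable = file.path(d, "rip_folds.csv"),
       report = file.path(d, "report.md"))
}

requireArtifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact '", path, "'; run the '", producer,
         "' stage first")
  }
  path
}

#' Pipeline stages
#'
#' Each `run*()` function executes one stage against the configuration's
#' `outputDir`, writes its artifacts, and records a manifest with content
#' hashes. Stages read only the files written by their upstream stages, so
#' any stage can be rerun in isolation.
#'
#' \describe{
#'   \item{`runSimulate()`}{bulk TSVs, single-cell MTX triplet, truth
#'     JSONs.}
#'   \item{`runDerive()`}{per-model DE CSVs, consensus signature GMT,
#'     Euler-region counts JSON, top-gene table.}
#'   \item{`runBenchmark()`}{NES grid CSV for the derived signature plus
#'     size-matched random decoys and any extra GMT signatures; RNK
#'     export of the ranked lists.}
#'   \item{`runScoreCells()`}{QC report JSON, per-cell scores and
#'     senescence calls CSVs, per-group fraction table, score-correlation
#'     stats.}
#'   \item{`runKnockout()`}{network edge list, perturbation profile CSV,
#'     top-gene list.}
#'   \item{`runRip()`}{fold-enrichment table from a Ct CSV (defaults to
#'     the bundled synthetic example).}
#'   \item{`runReport()`}{a single markdown report assembling the Euler
#'     counts, top-gene table, NES grid, per-group senescent fractions
#'     and RIP folds; errors listing the missing artifacts (and the
#'     stages that produce them) when upstream outputs are absent.}
#' }
#'
#' @param config configuration list from [loadRunConfig()].
#' @param runDir for `runReport()`: the run directory.
#' @return each stage invisibly returns its main artifact paths.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config = defaultRunConfig()) {
  p <- pipePaths(config)
  dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  seed <- stageSeed(config$seed, "simulate")
  b <- config$simulate$bulk
  bulkCfg <- bulkSimConfig(
    nGenes = b$nGenes, nDonors = b$nDonors, models = b$models,
    nSharedUp = b$nSharedUp, nSharedDown = b$nSharedDown,
    nModelSpecific = b$nModelSpecific, effectLog2fc = b$effectLog2fc,
    residualSd = b$residualSd, donorSd = b$donorSd, ifnArm = b$ifnArm,
    nIfnOverlapUp = b$nIfnOverlapUp, nIfnOverlapDown = b$nIfnOverlapDown,
    seed = stageSeed(seed, "bulk"))
  bulk <- simulateBulk(bulkCfg)
  writeBulkExpression(bulk$se, p$bulkPrefix)
  writeGroundTruth(bulk$truth, p$bulkTruth)

  cl <- config$simulate$cells
  cellCfg <- scSimConfig(
    nGenes = cl$nGenes,
    groups = data.frame(
      label = c("EP_prolif", "quiescent", "mid", "late"),
      nCells = rep(as.integer(cl$nCellsPerGroup), 4L),
      senescentFraction = c(0.01, 0.0, 0.29, 0.77)),
    signatureShift = cl$signatureShift,
    targetSaspCorr = cl$targetSaspCorr, nbDispersion = cl$nbDispersion,
    librarySizeMean = cl$librarySizeMean, qcViolators = cl$qcViolators,
    nSignatureGenes = cl$nSignatureGenes, nSaspGenes = cl$nSaspGenes,
    seed = stageSeed(seed, "cells"))
  cells <- simulateCells(cellCfg)
  writeCellDataset(cells$sce, p$cellsDir)
  writeGroundTruth(cells$truth, p$cellsTruth)

  files <- c(paste0(p$bulkPrefix, "_expression.tsv"),
             paste0(p$bulkPrefix, "_samples.tsv"), p$bulkTruth,
             file.path(p$cellsDir, c("matrix.mtx", "genes.tsv",
                                     "barcodes.tsv", "cellmeta.tsv")),
             p$cellsTruth)
  writeManifest(p$dir, "simulate", config$simulate, seed, files)
  invisible(files)
}

#' @rdname pipeline
#' @export
runDerive <- function(config = defaultRunConfig()) {
  p <- pipePaths(config)
  requireArtifact(paste0(p$bulkPrefix, "_expression.tsv"), "simulate")
  se <- readBulkExpression(p$bulkPrefix)
  d <- config$derive
  models <- setdiff(unique(SummarizedExperiment::colData(se)$model), "ifn")
  results <- list()
  deFiles <- character()
  for (m in models) {
    de <- differentialExpression(se, m, fcThreshold = d$fcThreshold,
                                 pThreshold = d$pThreshold,
                                 paired = d$paired)
    f <- paste0(p$dePrefix, "_", m, ".csv")
    writeDEResults(de, f)
    deFiles <- c(deFiles, f)
    results[[m]] <- de
  }
  cons <- deriveConsensus(results, name = d$name)
  writeGMT(cons$signature, p$gmt)
  jsonlite::write_json(lapply(cons$overlapCounts, as.list), p$euler,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  top <- topSignatureGenes(cons$signature, results,
                           n = min(d$topN, length(upGenes(cons$signature))))
  write.csv(top, p$topGenes, row.names = FALSE)

  if ("ifn" %in% SummarizedExperiment::colData(se)$model) {
    ifnDe <- differentialExpression(se, "ifn", conditions = c("IFN", "EP"),
                                    fcThreshold = d$fcThreshold,
                                    pThreshold = d$pThreshold)
    f <- paste0(p$dePrefix, "_ifn.csv")
    writeDEResults(ifnDe, f)
    deFiles <- c(deFiles, f)
    ov <- intersectWithTreatment(cons$signature, ifnDe)
    jsonlite::write_json(ov, file.path(p$dir, "ifn_overlap.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    deFiles <- c(deFiles, file.path(p$dir, "ifn_overlap.json"))
  }
  files <- c(deFiles, p$gmt, p$euler, p$topGenes)
  writeManifest(p$dir, "derive", config$derive,
                stageSeed(config$seed, "derive"), files)
  invisible(files)
}

#' @rdname pipeline
#' @export
runBenchmark <- function(config = defaultRunConfig()) {
  p <- pipePaths(config)
  requireArtifact(p$gmt, "derive")
  requireArtifact(paste0(p$bulkPrefix, "_expression.tsv"), "simulate")
  seed <- stageSeed(config$seed, "benchmark")
  se <- readBulkExpression(p$bulkPrefix)
  sigs <- readGMT(p$gmt)
  for (f in config$benchmark$signatureFiles) {
    sigs <- c(sigs, readGMT(f))
  }
  # size-matched random decoys for context
  set.seed(stageSeed(seed, "decoys"))
  main <- sigs[[1L]]
  for (i in seq_len(config$benchmark$nDecoys)) {
    nUp <- max(1L, length(upGenes(main)))
    decoyUp <- sample(rownames(se), nUp)
    sigs[[paste0("decoy", i)]] <- GeneSignature(paste0("decoy", i),
                                                up = decoyUp)
  }
  models <- setdiff(unique(SummarizedExperiment::colData(se)$model), "ifn")
  datasets <- lapply(setNames(nm = models), function(m) {
    list(se = se, conditions = c("senescent", "EP"), model = m)
  })
  bench <- benchmarkSignatures(sigs, datasets,
                               nPerm = config$benchmark$nPerm, seed = seed)
  write.csv(bench, p$benchmark, row.names = FALSE)
  rnkFiles <- vapply(models, function(m) {
    f <- file.path(p$dir, paste0("ranked_", m, ".rnk"))
    writeRNK(rankGenes(se, model = m), f)
    f
  }, character(1))
  files <- c(p$benchmark, rnkFiles)
  writeManifest(p$dir, "benchmark", config$benchmark, seed, files)
  invisible(files)
}

#' @rdname pipeline
#' @export
runScoreCells <- function(config = defaultRunConfig()) {
  p <- pipePaths(config)
  requireArtifact(file.path(p$cellsDir, "matrix.mtx"), "simulate")
  requireArtifact(p$cellsTruth, "simulate")
  seed <- stageSeed(config$seed, "score-cells")
  sce <- readCellDataset(p$cellsDir)
  truth <- readGroundTruth(p$cellsTruth)
  s <- config$scoreCells
  thr <- qcPreset(s$qcPreset, nGenes = nrow(sce))
  qc <- qcFilter(sce, thr)
  jsonlite::write_json(qc$report, p$qcReport, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  sce <- normalizeLog(qc$sce, targetSum = s$targetSum)
  sig <- GeneSignature("planted_signature", up = truth$signatureGenes)
  sasp <- GeneSignature("planted_sasp", up = truth$saspGenes)
  sigScores <- scoreCells(sce, sig, rMax = s$rMax)
  saspScores <- scoreCells(sce, sasp, rMax = s$rMax)
  write.csv(data.frame(barcode = colnames(sce),
                       group = SummarizedExperiment::colData(sce)$group,
                       signatureScore = unname(sigScores),
                       saspScore = unname(saspScores)),
            p$scores, row.names = FALSE)
  corr <- correlateScores(sigScores, saspScores)
  call <- annotateSenescence(sigScores,
                             groups = SummarizedExperiment::colData(sce)$group,
                             seed = seed)
  write.csv(data.frame(barcode = colnames(sce),
                       posterior = posteriors(call),
                       senescent = senescentLabels(call)),
            p$calls, row.names = FALSE)
  frac <- groupFractions(call)
  write.csv(data.frame(group = names(frac), fractionSenescent = unname(frac)),
            p$fractions, row.names = FALSE)
  jsonlite::write_json(list(pearsonR = corr$r, p = corr$p, n = corr$n,
                            annotationMethod = call@method),
                       p$scoreStats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(p$qcReport, p$scores, p$calls, p$fractions, p$scoreStats)
  writeManifest(p$dir, "score-cells", config$scoreCells, seed, files)
  invisible(files)
}

#' @rdname pipeline
#' @export
runKnockout <- function(config = defaultRunConfig()) {
  p <- pipePaths(config)
  requireArtifact(file.path(p$cellsDir, "matrix.mtx"), "simulate")
  seed <- stageSeed(config$seed, "knockout")
  sce <- readCellDataset(p$cellsDir)
  truth <- readGroundTruth(p$cellsTruth)
  k <- config$knockout
  target <- k$target
  if (is.null(target)) target <- truth$signatureGenes[[1L]]
  sce <- normalizeLog(sce)
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  v <- apply(x, 1L, var)
  subset <- rownames(x)[order(-v, rownames(x))][
    seq_len(min(k$nGenes, nrow(x)))]
  subset <- union(subset[seq_len(min(k$nGenes - 1L, length(subset)))],
                  target)
  net <- buildNetwork(x, geneSubset = subset, nPcs = k$nPcs,
                      ridge = k$ridge,
                      sparsityQuantile = k$sparsityQuantile)
  writeNetwork(net, p$network)
  prof <- perturbationProfile(net, knockout(net, target), target = target,
                              alpha = k$alpha, horizon = k$horizon)
  write.csv(profileTable(prof), p$profile, row.names = FALSE)
  knockoutReport(prof, topN = min(k$topN, length(netGenes(net)) - 1L),
                 geneListFile = p$koGenes)
  files <- c(p$network, p$profile, p$koGenes)
  writeManifest(p$dir, "knockout", config$knockout, seed, files)
  invisible(files)
}

#' @rdname pipeline
#' @export
runRip <- function(config = defaultRunConfig()) {
  p <- pipePaths(config)
  dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  input <- config$rip$input
  if (is.null(input)) {
    input <- system.file("extdata", "rip_ct_synthetic.csv",
                         package = "senesig")
  }
  ct <- readCtTable(input)
  folds <- ripFoldTable(ct, dilutionFactor = config$rip$dilutionFactor)
  write.csv(folds, p$ripTable, row.names = FALSE)
  writeManifest(p$dir, "rip", config$rip, stageSeed(config$seed, "rip"),
                p$ripTable)
  invisible(p$ripTable)
}

mdTable <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  c(header, sep, rows)
}

#' @rdname pipeline
#' @export
runReport <- function(runDir) {
  p <- pipePaths(list(outputDir = runDir))
  expected <- c(euler = "derive", topGenes = "derive",
                benchmark = "benchmark", fractions = "score-cells",
                qcReport = "score-cells", ripTable = "rip")
  missing <- names(expected)[!vapply(names(expected), function(nm) {
    file.exists(p[[nm]])
  }, logical(1))]
  if (length(missing)) {
    stop("cannot build report; missing artifacts:\n",
         paste(sprintf("  %s (produced by '%s')", unlist(p[missing]),
                       expected[missing]), collapse = "\n"))
  }
  euler <- jsonlite::read_json(p$euler, simplifyVector = TRUE)
  top <- read.csv(p$topGenes)
  bench <- read.csv(p$benchmark)
  frac <- read.csv(p$fractions)
  qc <- jsonlite::read_json(p$qcReport, simplifyVector = TRUE)
  rip <- read.csv(p$ripTable)
  lines <- c(
    "# Senescence signature pipeline report", "",
    "## Consensus signature: Euler-region counts (upregulated)", "",
    mdTable(data.frame(region = names(euler$up),
                       genes = unlist(euler$up))), "",
    "## Consensus signature: Euler-region counts (downregulated)", "",
    mdTable(data.frame(region = names(euler$down),
                       genes = unlist(euler$down))), "",
    sprintf("Consensus up-set size: %d genes; down-set size: %d genes.",
            as.integer(euler$up[["all"]]),
            as.integer(euler$down[["all"]])), "",
    "## Top signature genes by mean log2 fold change", "",
    mdTable(top), "",
    "## Signature benchmarking (NES grid)", "",
    mdTable(bench[, c("signature", "direction", "dataset", "nes",
                      "pPerm")]), "",
    "## Single-cell QC", "",
    sprintf("%d of %d cells retained (removed: %s).",
            as.integer(qc$nRetained), as.integer(qc$nInput),
            paste(sprintf("%s=%d", names(qc$removed),
                          as.integer(unlist(qc$removed))),
                  collapse = ", ")), "",
    "## Senescent fraction per group", "",
    mdTable(frac), "",
    "## RIP fold enrichment", "",
    mdTable(rip), "")
  writeLines(lines, p$report)
  invisible(p$report)
}
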