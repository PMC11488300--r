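# Single-cell QC, normalization, rank-based scoring, correlation,
# mixture annotation, and group comparison.

test_that("threshold constructors validate their windows", {
  expect_error(qcThresholds(500, 500, 0.01, 0.2), "minGenes")
  expect_error(qcThresholds(500, 6000, 0.2, 0.2), "minMito")
  thr <- qcPreset("mouse-retina")
  expect_equal(thr$minGenes, 500)
  expect_equal(thr$maxMito, 0.20)
  thr2 <- qcPreset("human-ecfc")
  expect_equal(thr2$maxGenes, 9000)
  expect_equal(thr2$maxMito, 0.10)
})

test_that("qcFilter removes planted violators exactly, attributed in order", {
  fx <- defaultCellsFixture()
  rep <- fx$qc$report
  expect_equal(rep$nInput, 2840)
  expect_equal(rep$nRetained, 2800)
  expect_equal(unname(rep$removed), c(10L, 10L, 10L, 10L))
  expect_setequal(setdiff(colnames(fx$sim$sce), colnames(fx$qc$sce)),
                  fx$sim$truth$qcViolators$barcode)
})

test_that("boundary cells survive the strict inequalities and filtering is idempotent", {
  thr <- qcThresholds(100, 1000, 0.01, 0.10)
  counts <- matrix(1L, nrow = 5, ncol = 4)
  sce <- makeTinySce(counts,
                     detected = c(100, 1000, 99, 1001),
                     mito = c(0.01, 0.10, 0.05, 0.05))
  out <- qcFilter(sce, thr)
  # boundary-value cells (first two) retained, out-of-window cells removed
  expect_equal(colnames(out$sce), colnames(sce)[1:2])
  expect_equal(unname(out$report$removed), c(1L, 1L, 0L, 0L))
  again <- qcFilter(out$sce, thr)
  expect_identical(colnames(again$sce), colnames(out$sce))
  expect_equal(sum(again$report$removed), 0L)
  # multi-criterion cells are attributed to the first failing criterion
  sce2 <- makeTinySce(matrix(1L, 2, 1), detected = 50, mito = 0.5)
  expect_warning(out2 <- qcFilter(sce2, thr), "every cell")
  expect_equal(unname(out2$report$removed), c(1L, 0L, 0L, 0L))
})

test_that("normalization matches a hand-computed example and is scale invariant", {
  counts <- matrix(c(1, 2, 7,
                     0, 5, 5), nrow = 3,
                   dimnames = list(c("Ga", "Gb", "Gc"), c("c1", "c2")))
  sce <- makeTinySce(counts)
  out <- normalizeLog(sce, targetSum = 10)
  lc <- as.matrix(SummarizedExperiment::assay(out, "logcounts"))
  expect_equal(unname(lc[, 1]), log1p(c(1, 2, 7)), tolerance = 1e-12)
  expect_equal(unname(lc[, 2]), log1p(c(0, 5, 5)), tolerance = 1e-12)
  doubled <- makeTinySce(counts * 2)
  lc2 <- as.matrix(SummarizedExperiment::assay(
    normalizeLog(doubled, targetSum = 10), "logcounts"))
  expect_equal(lc2, lc, tolerance = 1e-12)
  # a cell concentrated in one gene carries the whole target sum there
  one <- makeTinySce(matrix(c(0, 0, 4), nrow = 3))
  lco <- as.matrix(SummarizedExperiment::assay(normalizeLog(one, 10),
                                               "logcounts"))
  expect_equal(unname(lco[, 1]), c(0, 0, log1p(10)), tolerance = 1e-12)
  zero <- makeTinySce(cbind(c(1, 1, 1), c(0, 0, 0)))
  expect_warning(normalizeLog(zero), "zero-count")
})

test_that("rank score hits its extremes and respects clipping", {
  # 10 genes, signature genes occupy the top ranks of cell 1
  counts <- matrix(0, nrow = 10, ncol = 2,
                   dimnames = list(sprintf("G%02d", 1:10), c("c1", "c2")))
  counts[1:3, 1] <- c(30, 20, 10)
  counts[4:10, 2] <- 7:1
  sce <- normalizeLog(makeTinySce(counts), targetSum = 100)
  sig <- GeneSignature("s", up = sprintf("G%02d", 1:3))
  sc <- scoreCells(sce, sig, rMax = 5)
  expect_equal(unname(sc["c1"]), 1, tolerance = 1e-12)
  # single-gene signature entirely beyond rMax scores exactly 0
  sig1 <- GeneSignature("s1", up = "G01")
  sc1 <- scoreCells(sce, sig1, rMax = 5)
  expect_equal(unname(sc1["c2"]), 0, tolerance = 1e-12)
  expect_error(scoreCells(sce, GeneSignature("none", up = "ABSENT")),
               "none")
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("rank score is invariant to monotone transformation of expression", {
  fx <- defaultCellsFixture()
  sce <- fx$sce[, 1:50]
  base <- scoreCells(sce, fx$sig)
  mono <- sce
  lc <- SummarizedExperiment::assay(mono, "logcounts")
  SummarizedExperiment::assay(mono, "logcounts") <- expm1(lc)  # exp, shifted
  trans <- scoreCells(mono, fx$sig)
  expect_equal(unname(base), unname(trans), tolerance = 1e-12)
})

test_that("senescent cells score above proliferating cells for the planted signature", {
  fx <- defaultCellsFixture()
  grp <- SummarizedExperiment::colData(fx$sce)$group
  expect_gt(mean(fx$sigScores[grp == "late"]),
            mean(fx$sigScores[grp == "EP_prolif"]))
  sen <- fx$sim$truth$senescent[colnames(fx$sce)]
  expect_gt(mean(fx$sigScores[sen]), mean(fx$sigScores[!sen]) + 0.1)
})

test_that("correlation matches the textbook formula and its edge cases", {
  set.seed(31)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  co <- correlateScores(x, y)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(co$r, oracle, tolerance = 1e-12)
  expect_equal(co$p, cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(correlateScores(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(correlateScores(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(correlateScores(x, rep(1, 40)), "zero variance")
  expect_error(correlateScores(x[1:2], y[1:2]), "length")
})

test_that("signature and SASP scores recover the planted correlation", {
  fx <- defaultCellsFixture()
  co <- correlateScores(fx$sigScores, fx$saspScores)
  expect_lt(abs(co$r - 0.8), 0.1)
  expect_lt(co$p, 1e-10)
})

test_that("the mixture model recovers a planted mixing fraction", {
  set.seed(13)
  n <- 1000
  lab <- runif(n) < 0.3
  x <- ifelse(lab, rnorm(n, 2, 0.4), rnorm(n, 0, 0.4))
  call <- annotateSenescence(x, seed = 5)
  expect_equal(call@method, "gmm-em")
  expect_lt(abs(mean(senescentLabels(call)) - 0.3), 0.05)
  expect_gt(mean(lab == senescentLabels(call)), 0.95)
})

test_that("fraction recovery error shrinks with component separation", {
  set.seed(19)
  n <- 600
  err <- vapply(c(1.0, 2.0, 4.0), function(sep) {
    lab <- runif(n) < 0.4
    x <- ifelse(lab, rnorm(n, sep, 0.5), rnorm(n, 0, 0.5))
    call <- annotateSenescence(x, seed = 3)
    abs(mean(senescentLabels(call)) - mean(lab))
  }, numeric(1))
  expect_true(err[3] <= err[1])
  expect_lt(err[3], 0.02)
})

test_that("degenerate scores fall back to a median split with a warning", {
  x <- rep(0.5, 50)
  expect_warning(call <- annotateSenescence(x, seed = 1), "median split")
  expect_equal(call@method, "median-split")
  expect_equal(mean(senescentLabels(call)), 0.5)
})

test_that("per-group senescent fractions recover the planted staging", {
  fx <- defaultCellsFixture()
  call <- annotateSenescence(
    fx$sigScores, groups = SummarizedExperiment::colData(fx$sce)$group,
    seed = 1)
  frac <- groupFractions(call)[c("EP_prolif", "quiescent", "mid", "late")]
  planted <- c(0.01, 0.00, 0.29, 0.77)
  expect_true(all(abs(frac - planted) <= 0.05))
})

test_that("group comparison reports monotone planted ordering and sane nulls", {
  fx <- defaultCellsFixture()
  grp <- SummarizedExperiment::colData(fx$sce)$group
  keep <- grp %in% c("EP_prolif", "mid", "late")
  cmp <- compareGroups(fx$sigScores[keep], grp[keep])
  means <- setNames(cmp$summary$mean, cmp$summary$group)
  expect_true(means[["EP_prolif"]] < means[["mid"]])
  expect_true(means[["mid"]] < means[["late"]])
  expect_true(all(cmp$tests$padj <= 1))
  # identical distributions: no signal
  set.seed(41)
  x <- rnorm(60)
  cmp2 <- compareGroups(c(x, x), rep(c("a", "b"), each = 60))
  expect_equal(cmp2$tests$medianDiff, 0, tolerance = 1e-12)
  expect_gt(cmp2$tests$padj, 0.9)
  # groups under 3 cells are dropped with a warning, others still compared
  expect_warning(
    cmp3 <- compareGroups(rnorm(32), c(rep("a", 20), rep("b", 2),
                                       rep("c", 10))),
    "excluded")
  expect_setequal(cmp3$summary$group, c("a", "c"))
})
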