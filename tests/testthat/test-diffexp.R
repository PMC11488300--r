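# Differential expression, consensus derivation, and treatment overlap.

makeBulkSe <- function(values, condition, donor = NULL, model = "m1") {
  if (is.null(donor)) donor <- sprintf("D%d", seq_along(condition))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(donor = donor, model = model,
                                   condition = condition,
                                   row.names = sprintf("S%02d",
                                                       seq_along(condition))))
}

test_that("identical groups give zero fold changes and no significant genes", {
  set.seed(1)
  half <- matrix(rnorm(60), nrow = 10)
  x <- cbind(half, half)
  rownames(x) <- sprintf("G%06d", 1:10)
  se <- makeBulkSe(x, rep(c("EP", "senescent"), each = 6),
                   donor = rep(sprintf("D%d", 1:6), 2))
  de <- suppressMessages(differentialExpression(se, "m1"))
  expect_true(all(de$log2fc == 0))
  expect_false(any(de$significantUp | de$significantDown))
})

test_that("Welch statistics match stats::t.test on a hand-set gene and random instances", {
  ep <- c(1.0, 1.1, 0.9); sen <- c(3.0, 3.2, 2.8)
  x <- rbind(G000001 = c(ep, sen))
  se <- makeBulkSe(x, rep(c("EP", "senescent"), each = 3),
                   donor = rep(c("D1", "D2", "D3"), 2))
  de <- differentialExpression(se, "m1")
  oracle <- t.test(sen, ep)
  expect_equal(de$log2fc, 2.0, tolerance = 1e-12)
  expect_equal(de$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(de$p, oracle$p.value, tolerance = 1e-12)
  expect_true(de$significantUp)

  set.seed(42)
  for (i in 1:100) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = runif(1, -2, 2))
    x <- rbind(G000001 = c(b, a))
    se <- makeBulkSe(x, c(rep("EP", nb), rep("senescent", na)),
                     donor = sprintf("D%d", seq_len(na + nb)))
    de <- differentialExpression(se, "m1")
    or <- t.test(a, b)
    expect_equal(de$p, or$p.value, tolerance = 1e-10)
    expect_equal(de$t, unname(or$statistic), tolerance = 1e-10)
  }
})

test_that("paired and pooled variants match their stats:: counterparts", {
  set.seed(7)
  a <- rnorm(4, 1); b <- rnorm(4)
  x <- rbind(G000001 = c(b, a))
  se <- makeBulkSe(x, rep(c("EP", "senescent"), each = 4),
                   donor = rep(sprintf("D%d", 1:4), 2))
  deP <- differentialExpression(se, "m1", paired = TRUE)
  expect_equal(deP$p, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  deV <- differentialExpression(se, "m1", varEqual = TRUE)
  expect_equal(deV$p, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("insufficient replication raises an informative error", {
  x <- matrix(rnorm(3), nrow = 1,
              dimnames = list("G000001", NULL))
  se <- makeBulkSe(x, c("EP", "senescent", "senescent"))
  expect_error(differentialExpression(se, "m1"), "insufficient replication")
})

test_that("consensus intersection follows brute-force set arithmetic", {
  mk <- function(up) {
    genes <- sprintf("g%d", 1:6)
    data.frame(gene = genes, log2fc = ifelse(genes %in% up, 2, 0),
               t = 5, p = ifelse(genes %in% up, 0.01, 0.9),
               significantUp = genes %in% up,
               significantDown = FALSE)
  }
  res <- list(A = mk(c("g1", "g2", "g3")), B = mk(c("g2", "g3", "g4")),
              C = mk(c("g2", "g3")))
  cons <- suppressWarnings(deriveConsensus(res))
  expect_setequal(upGenes(cons$signature), c("g2", "g3"))
  oc <- cons$overlapCounts$up
  expect_equal(unname(oc[c("A", "B", "C")]), c(3, 3, 2))
  expect_equal(unname(oc["A&B"]), 2)
  expect_equal(unname(oc["A&C"]), 2)
  expect_equal(unname(oc["all"]), 2)
})

test_that("consensus equals each model's set when all models agree", {
  fx <- defaultBulkFixture()
  one <- fx$results$replicative
  res <- list(A = one, B = one, C = one)
  cons <- deriveConsensus(res)
  expect_setequal(upGenes(cons$signature),
                  one$gene[one$significantUp])
  expect_equal(unname(cons$overlapCounts$up[["all"]]),
               sum(one$significantUp))
})

test_that("consensus is a subset of every model's significant set", {
  fx <- defaultBulkFixture()
  sig <- fx$consensus$signature
  for (m in names(fx$results)) {
    expect_true(all(upGenes(sig) %in%
                      fx$results[[m]]$gene[fx$results[[m]]$significantUp]))
    expect_true(all(downGenes(sig) %in%
                      fx$results[[m]]$gene[fx$results[[m]]$significantDown]))
  }
})

test_that("planted programs drive recovery well above the null, with no false members", {
  fx <- defaultBulkFixture()
  truth <- fx$sim$truth
  for (m in names(fx$results)) {
    up <- fx$results[[m]]$gene[fx$results[[m]]$significantUp]
    plantedUp <- union(truth$sharedUp, truth$modelSpecific[[m]]$up)
    expect_gt(mean(plantedUp %in% up), 0.7)
  }
  sig <- fx$consensus$signature
  expect_gt(mean(truth$sharedUp %in% upGenes(sig)), 0.5)
  expect_gt(mean(truth$sharedDown %in% downGenes(sig)), 0.4)
  # members not planted as shared stay rare
  expect_lt(mean(!upGenes(sig) %in% truth$sharedUp), 0.05)
  expect_lt(mean(!downGenes(sig) %in% truth$sharedDown), 0.05)
})

test_that("null data flag near the nominal rate per model and almost never intersect", {
  sim <- simulateBulk(bulkSimConfig(nGenes = 2000, effectLog2fc = 0,
                                    seed = 8))
  res <- lapply(setNames(nm = c("replicative", "xray", "etoposide")),
                function(m) differentialExpression(sim$se, m))
  fracs <- vapply(res, function(d) mean(d$significantUp | d$significantDown),
                  numeric(1))
  expect_true(all(fracs <= 0.05 + 3 * sqrt(0.05 * 0.95 / 2000)))
  cons <- suppressWarnings(deriveConsensus(res))
  expect_lte(length(upGenes(cons$signature)) +
               length(downGenes(cons$signature)), 2)
})

test_that("recovery power is monotone in effect size", {
  rec <- vapply(c(0.8, 1.6, 2.4), function(eff) {
    sim <- simulateBulk(bulkSimConfig(nGenes = 600, nSharedUp = 50,
                                      nSharedDown = 50,
                                      nModelSpecific = 20,
                                      effectLog2fc = eff, seed = 21))
    res <- lapply(setNames(nm = c("replicative", "xray", "etoposide")),
                  function(m) differentialExpression(sim$se, m))
    cons <- suppressWarnings(deriveConsensus(res))
    mean(sim$truth$sharedUp %in% upGenes(cons$signature))
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
})

test_that("top genes are ordered by mean log2fc with lexicographic ties", {
  mk <- function(fc) {
    data.frame(gene = c("Ga", "Gb", "Gc"), log2fc = fc, t = 5, p = 0.001,
               significantUp = TRUE, significantDown = FALSE)
  }
  res <- list(A = mk(c(2.0, 3.1, 2.0)), B = mk(c(2.0, 3.1, 2.0)))
  cons <- deriveConsensus(res)
  top <- topSignatureGenes(cons$signature, res, n = 3)
  expect_equal(top$gene, c("Gb", "Ga", "Gc"))
  expect_equal(top$meanLog2fc, c(3.1, 2.0, 2.0))
  top1 <- topSignatureGenes(cons$signature, res, n = 1)
  expect_equal(top1$gene, "Gb")
  expect_message(topSignatureGenes(cons$signature, res, n = 10),
                 "exceeds")
})

test_that("treatment overlap follows exact set intersection", {
  sig <- GeneSignature("s", up = c("g1", "g2"), down = c("g5", "g6"))
  trt <- data.frame(gene = sprintf("g%d", 1:6), log2fc = 0, t = 0, p = 1,
                    significantUp = FALSE, significantDown = FALSE)
  ov <- intersectWithTreatment(sig, trt)
  expect_length(ov$up, 0)
  expect_length(ov$down, 0)
  trt$significantUp <- trt$gene %in% c("g1", "g2")
  trt$significantDown <- trt$gene %in% c("g5", "g6")
  ov <- intersectWithTreatment(sig, trt)
  expect_equal(ov$up, c("g1", "g2"))
  expect_equal(ov$down, c("g5", "g6"))
})

test_that("the interferon arm shares planted genes with the consensus", {
  fx <- defaultBulkFixture()
  ifnDe <- differentialExpression(fx$sim$se, "ifn",
                                  conditions = c("IFN", "EP"))
  ov <- intersectWithTreatment(fx$consensus$signature, ifnDe)
  # overlap is dominated by planted interferon-shared genes
  expect_lte(sum(!ov$up %in% fx$sim$truth$ifnUp), 2)
  expect_lte(sum(!ov$down %in% fx$sim$truth$ifnDown), 2)
  expect_gt(sum(ov$up %in% fx$sim$truth$ifnUp),
            length(fx$sim$truth$ifnUp) / 2)
})

test_that("signatures round-trip through GMT preserving order", {
  fx <- defaultBulkFixture()
  sig <- fx$consensus$signature
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sig, path)
  back <- readGMT(path)
  expect_length(back, 1)
  expect_identical(upGenes(back$consensus), upGenes(sig))
  expect_identical(downGenes(back$consensus), downGenes(sig))
})
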