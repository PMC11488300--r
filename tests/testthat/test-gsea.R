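# Preranked GSEA: running sum, permutation null, NES, benchmarking, ISM.

test_that("enrichment score matches the brute-force oracle on all subsets of an 8-gene list", {
  set.seed(3)
  metric <- sort(rnorm(8), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("g%d", 1:8), metric = metric)
  for (k in 1:7) {
    sets <- combn(8, k)
    for (j in seq_len(ncol(sets))) {
      hits <- seq_len(8) %in% sets[, j]
      es <- enrichmentScore(ranked, ranked$gene[hits])$es
      expect_es_equal(es, bruteForceES(metric, hits))
    }
  }
})

test_that("worked running-sum examples give the expected scores", {
  rl <- data.frame(gene = sprintf("g%d", 1:6),
                   metric = c(3, 2, 1, -1, -2, -3))
  res <- enrichmentScore(rl, c("g1", "g4"))
  expect_equal(res$es, 0.75, tolerance = 1e-12)
  expect_equal(res$hitIndices, c(1L, 4L))
  expect_equal(res$leadingEdge, "g1")
  # single hit at the top scores exactly 1
  expect_equal(enrichmentScore(rl, "g1")$es, 1.0, tolerance = 1e-12)
  # antisymmetry under metric negation + order reversal
  rlRev <- data.frame(gene = rev(rl$gene), metric = rev(-rl$metric))
  expect_equal(enrichmentScore(rlRev, c("g1", "g4"))$es, -0.75,
               tolerance = 1e-12)
  expect_error(enrichmentScore(rl, "absent"), "no genes")
  expect_error(enrichmentScore(rl, rl$gene), "whole ranked list")
})

test_that("enrichment scores agree with fgsea on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  for (i in 1:20) {
    n <- 50
    metric <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    ranked <- data.frame(gene = sprintf("g%03d", 1:n), metric = metric)
    sel <- sort(sample.int(n, sample(3:15, 1)))
    ours <- enrichmentScore(ranked, ranked$gene[sel])$es
    ref <- fgsea::calcGseaStat(setNames(metric, ranked$gene), sel,
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo permutation p matches the exhaustive null on a small universe", {
  set.seed(5)
  metric <- sort(rnorm(8, mean = 0.5), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("g%d", 1:8), metric = metric)
  geneSet <- ranked$gene[c(1, 2, 5)]
  nPerm <- 2000
  er <- normalizedEnrichment(ranked, geneSet, nPerm = nPerm, seed = 1)
  # exhaustive null over all C(8,3) = 56 same-size subsets
  nullEs <- apply(combn(8, 3), 2L, function(ix) {
    bruteForceES(metric, seq_len(8) %in% ix)
  })
  same <- sign(nullEs) == sign(esValue(er))
  pExh <- sum(abs(nullEs[same]) >= abs(esValue(er))) / sum(same)
  expect_lt(abs(pPerm(er) - pExh), 2 / sqrt(nPerm))
})

test_that("the permutation null is centered and super-uniform for random sets", {
  set.seed(17)
  n <- 200
  metric <- sort(rnorm(n), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("g%03d", 1:n), metric = metric)
  nPerm <- 400
  res <- vapply(1:500, function(i) {
    gs <- sample(ranked$gene, 15)
    er <- normalizedEnrichment(ranked, gs, nPerm = nPerm, seed = 1000 + i)
    c(nesValue(er), pPerm(er))
  }, numeric(2))
  expect_lt(abs(mean(res[1, ], na.rm = TRUE)), 0.2)
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(res[2, ] <= alpha), alpha + 3 / sqrt(nPerm))
  }
})

test_that("ES and NES are invariant to positive rescaling of the metric", {
  set.seed(23)
  n <- 60
  metric <- sort(rnorm(n), decreasing = TRUE)
  ranked <- data.frame(gene = sprintf("g%03d", 1:n), metric = metric)
  scaled <- ranked
  scaled$metric <- ranked$metric * 7.3
  gs <- sample(ranked$gene, 8)
  for (w in c(0, 1)) {
    a <- normalizedEnrichment(ranked, gs, nPerm = 200, seed = 4,
                              weightExponent = w)
    b <- normalizedEnrichment(scaled, gs, nPerm = 200, seed = 4,
                              weightExponent = w)
    expect_equal(esValue(a), esValue(b), tolerance = 1e-12)
    expect_equal(nesValue(a), nesValue(b), tolerance = 1e-12)
  }
})

test_that("permutation results are bit-reproducible for a fixed seed", {
  fx <- defaultBulkFixture()
  ranked <- rankGenes(fx$sim$se, model = "xray")
  a <- normalizedEnrichment(ranked, fx$sim$truth$sharedUp, nPerm = 150,
                            seed = 99)
  b <- normalizedEnrichment(ranked, fx$sim$truth$sharedUp, nPerm = 150,
                            seed = 99)
  expect_identical(esValue(a), esValue(b))
  expect_identical(nesValue(a), nesValue(b))
  expect_identical(pPerm(a), pPerm(b))
})

test_that("ranking metric equals the DE t-statistic and orders planted genes first", {
  fx <- defaultBulkFixture()
  ranked <- rankGenes(fx$sim$se, model = "replicative")
  de <- fx$results$replicative
  expect_equal(setNames(ranked$metric, ranked$gene)[de$gene],
               setNames(de$t, de$gene), tolerance = 1e-12)
  expect_true(all(diff(ranked$metric) <= 0))
})

test_that("planted signatures score strongly in the expected directions", {
  fx <- defaultBulkFixture()
  ranked <- rankGenes(fx$sim$se, model = "replicative")
  up <- normalizedEnrichment(ranked, fx$sim$truth$sharedUp, nPerm = 500,
                             seed = 7)
  expect_gt(nesValue(up), 0)
  expect_lte(pPerm(up), 0.01)
  down <- normalizedEnrichment(ranked, fx$sim$truth$sharedDown, nPerm = 500,
                               seed = 8)
  expect_lt(nesValue(down), 0)
  expect_lte(pPerm(down), 0.01)
})

test_that("benchmark table has one row per signature direction and dataset", {
  fx <- defaultBulkFixture()
  sig <- GeneSignature("planted", up = fx$sim$truth$sharedUp,
                       down = fx$sim$truth$sharedDown)
  bench <- benchmarkSignatures(list(sig),
                               list(ds1 = list(se = fx$sim$se,
                                               conditions = c("senescent",
                                                              "EP"),
                                               model = "etoposide")),
                               nPerm = 150, seed = 2)
  expect_equal(nrow(bench), 2)
  expect_setequal(bench$direction, c("up", "down"))
  expect_gt(bench$nes[bench$direction == "up"], 0)
  expect_lt(bench$nes[bench$direction == "down"], 0)
})

test_that("ISM is centered on reference samples and separates the interferon arm", {
  fx <- defaultBulkFixture()
  se <- fx$sim$se
  cd <- SummarizedExperiment::colData(se)
  ism <- ismScore(se, fx$sim$truth$ifnUp, referenceCondition = "EP")
  expect_lt(abs(median(ism[cd$condition == "EP"])), 0.5)
  expect_gt(min(ism[cd$condition == "IFN"]),
            max(ism[cd$condition == "EP"]))
  # a single-gene panel reduces to that gene's z-score
  g <- fx$sim$truth$ifnUp[1L]
  x <- SummarizedExperiment::assay(se, "log2")
  ref <- cd$condition == "EP"
  z <- (x[g, ] - mean(x[g, ref])) / sd(x[g, ref])
  expect_equal(ismScore(se, g), z, tolerance = 1e-12)
})
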