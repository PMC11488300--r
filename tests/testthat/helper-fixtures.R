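# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# default bulk simulation, seed 1, with per-model DE results
defaultBulkFixture <- function() {
  memo("bulk1", function() {
    sim <- simulateBulk(bulkSimConfig(seed = 1))
    models <- c("replicative", "xray", "etoposide")
    res <- lapply(setNames(nm = models), function(m) {
      differentialExpression(sim$se, m)
    })
    list(sim = sim, results = res,
         consensus = deriveConsensus(res, name = "consensus"))
  })
}

# default single-cell lifespan simulation, seed 7, QC-filtered, normalized
# and scored for the planted signature and SASP programs
defaultCellsFixture <- function() {
  memo("cells7", function() {
    sim <- simulateCells(scSimConfig(seed = 7))
    thr <- qcPreset("synthetic-lifespan", nGenes = nrow(sim$sce))
    qc <- qcFilter(sim$sce, thr)
    sce <- normalizeLog(qc$sce)
    sig <- GeneSignature("planted_signature", up = sim$truth$signatureGenes)
    sasp <- GeneSignature("planted_sasp", up = sim$truth$saspGenes)
    list(sim = sim, qc = qc, sce = sce, sig = sig, sasp = sasp,
         sigScores = scoreCells(sce, sig), saspScores = scoreCells(sce, sasp))
  })
}

# brute-force weighted running-sum ES: independent of the package's
# candidate-position implementation
bruteForceES <- function(metric, hits, weightExponent = 1) {
  N <- length(metric)
  k <- sum(hits)
  w <- abs(metric)^weightExponent
  nr <- sum(w[hits])
  running <- numeric(N)
  val <- 0
  for (i in seq_len(N)) {
    val <- if (hits[i]) {
      val + (if (nr > 0) w[i] / nr else 1 / k)
    } else {
      val - 1 / (N - k)
    }
    running[i] <- val
  }
  maxv <- max(running); minv <- min(running)
  if (abs(maxv) >= abs(minv)) maxv else minv
}

# ES comparison robust to floating-point accumulation order: values agree
# to 1e-12, except at exact magnitude ties where only |ES| is defined
expect_es_equal <- function(es, oracle) {
  if (abs(es - oracle) < 1e-12) {
    testthat::expect_equal(es, oracle, tolerance = 1e-12)
  } else {
    testthat::expect_equal(abs(es), abs(oracle), tolerance = 1e-12)
  }
}

# tiny SingleCellExperiment with explicit QC metadata
makeTinySce <- function(counts, detected = NULL, mito = NULL,
                        group = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("G%06d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("CELL_%05d", seq_len(ncol(counts)))
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  cd$detectedGenes <- if (is.null(detected)) {
    Matrix::colSums(counts > 0)
  } else {
    detected
  }
  cd$mitoFraction <- if (is.null(mito)) rep(0.05, ncol(counts)) else mito
  if (!is.null(group)) cd$group <- group
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
}
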