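# Per-model differential expression and cross-model intersection into a
# consensus up/down senescence signature.

# Vectorized Welch / pooled / paired t-tests over the rows of two matrices.
# Returns t, df and the two-sided p per gene. The degenerate zero-variance,
# zero-difference case yields p = 1 by convention.
rowTTest <- function(a, b, paired = FALSE, varEqual = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  rowVars <- function(x) rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  if (paired) {
    stopifnot(na == nb)
    d <- a - b
    m <- rowMeans(d)
    v <- rowVars(d)
    se <- sqrt(v / na)
    df <- rep(na - 1, nrow(a))
    t <- m / se
  } else {
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowVars(a); vb <- rowVars(b)
    if (varEqual) {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- rep(na + nb - 2, nrow(a))
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
    }
    m <- ma - mb
    t <- m / se
  }
  degenerate <- !is.finite(t)
  zeroBoth <- degenerate & m == 0        # no variance, no difference
  t[zeroBoth] <- 0
  t[degenerate & m != 0] <- sign(m[degenerate & m != 0]) * Inf
  p <- 2 * pt(-abs(t), df)
  p[degenerate & m != 0] <- 0
  p[zeroBoth] <- 1
  if (any(zeroBoth)) {
    message(sum(zeroBoth),
            " gene(s) with zero variance and zero difference: p = 1 by",
            " convention")
  }
  list(t = t, df = df, p = p, diff = m)
}

#' Per-gene differential expression for one senescence model
#'
#' Compares log2 expression between two conditions of one model with a
#' two-sided Welch t-test per gene (optionally pooled-variance or, since
#' donors are matched across arms, paired by donor). Genes are called
#' significantly up when `log2fc > fcThreshold` and `p < pThreshold`
#' (strict inequalities), symmetrically for down. No multiple-testing
#' correction is applied by default, matching the raw p-value criterion of
#' the upstream microarray analysis; set `adjust = "BH"` to gate the flags
#' on Benjamini-Hochberg adjusted p-values instead.
#'
#' @param se `SummarizedExperiment` with assay `log2` and colData columns
#'   `donor`, `model`, `condition`.
#' @param model model label to subset to.
#' @param conditions length-2 character: the test condition and its
#'   control; `log2fc = mean(conditions[1]) - mean(conditions[2])`.
#' @param fcThreshold absolute log2 fold-change gate (strict).
#' @param pThreshold p-value gate (strict).
#' @param paired use a donor-paired t-test.
#' @param varEqual pooled-variance (Student) instead of Welch.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame, one row per gene in input order: `gene`, `log2fc`,
#'   `t`, `p`, `padj` (when adjusted), `significantUp`, `significantDown`.
#' @examples
#' sim <- simulateBulk(bulkSimConfig(nGenes = 400, nSharedUp = 15,
#'                                   nSharedDown = 20, nModelSpecific = 20,
#'                                   nIfnOverlapUp = 5, nIfnOverlapDown = 3,
#'                                   seed = 1))
#' de <- differentialExpression(sim$se, "replicative")
#' sum(de$significantUp)
#' @export
differentialExpression <- function(se, model,
                                   conditions = c("senescent", "EP"),
                                   fcThreshold = 1.0, pThreshold = 0.05,
                                   paired = FALSE, varEqual = FALSE,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(conditions) == 2L)
  cd <- SummarizedExperiment::colData(se)
  keep <- cd$model == model & cd$condition %in% conditions
  if (!any(keep)) stop("no samples for model '", model, "'")
  x <- SummarizedExperiment::assay(se, "log2")[, keep, drop = FALSE]
  cond <- cd$condition[keep]
  donor <- cd$donor[keep]
  ia <- cond == conditions[1L]
  ib <- cond == conditions[2L]
  if (sum(ia) < 2L || sum(ib) < 2L) {
    stop("insufficient replication: need >= 2 samples per arm, got ",
         sum(ia), " '", conditions[1L], "' and ", sum(ib), " '",
         conditions[2L], "'")
  }
  a <- x[, ia, drop = FALSE]
  b <- x[, ib, drop = FALSE]
  if (paired) {
    if (!setequal(donor[ia], donor[ib])) {
      stop("paired test requires matching donors in both arms")
    }
    b <- b[, match(donor[ia], donor[ib]), drop = FALSE]
  }
  tt <- rowTTest(a, b, paired = paired, varEqual = varEqual)
  res <- data.frame(gene = rownames(x), log2fc = tt$diff, t = tt$t, p = tt$p,
                    row.names = NULL)
  pGate <- res$p
  if (adjust == "BH") {
    res$padj <- p.adjust(res$p, method = "BH")
    pGate <- res$padj
  }
  res$significantUp <- res$log2fc > fcThreshold & pGate < pThreshold
  res$significantDown <- res$log2fc < -fcThreshold & pGate < pThreshold
  res
}

significantGenes <- function(de, direction = c("up", "down")) {
  direction <- match.arg(direction)
  col <- if (direction == "up") "significantUp" else "significantDown"
  de$gene[de[[col]]]
}

#' Derive a consensus signature by intersecting per-model DE results
#'
#' The consensus up-set is the intersection over all models of their
#' significantly upregulated genes (symmetrically for down). The up-set is
#' ordered by descending mean log2 fold change across models, the down-set
#' ascending. `overlapCounts` reports every region of the Euler
#' decomposition of the significant sets: per-model totals, all pairwise
#' intersections, and the full intersection, separately for up and down.
#'
#' @param perModelResults named list (>= 2 models) of data.frames from
#'   [differentialExpression()].
#' @param name label for the derived signature.
#' @return list with `signature` (a [GeneSignature-class]) and
#'   `overlapCounts` (list `up`/`down` of named integer vectors; pairwise
#'   regions are named `"modelA&modelB"`, the full intersection `"all"`).
#' @export
deriveConsensus <- function(perModelResults, name = "consensus") {
  stopifnot(length(perModelResults) >= 2L, !is.null(names(perModelResults)))
  models <- names(perModelResults)
  sets <- function(direction) {
    lapply(perModelResults, significantGenes, direction = direction)
  }
  eulerCounts <- function(sets) {
    counts <- vapply(sets, length, integer(1))
    for (i in seq_along(models)) {
      for (j in seq_along(models)) {
        if (i < j) {
          counts[[paste0(models[i], "&", models[j])]] <-
            length(intersect(sets[[i]], sets[[j]]))
        }
      }
    }
    counts[["all"]] <- length(Reduce(intersect, sets))
    counts
  }
  upSets <- sets("up"); downSets <- sets("down")
  up <- Reduce(intersect, upSets)
  down <- Reduce(intersect, downSets)
  if (length(up) == 0L && length(down) == 0L) {
    warning("empty consensus: no gene is significant in every model")
  }
  mfc <- meanLog2fc(perModelResults)
  up <- up[order(-mfc[up], up)]
  down <- down[order(mfc[down], down)]
  list(signature = GeneSignature(name, up = up, down = down),
       overlapCounts = list(up = eulerCounts(upSets),
                            down = eulerCounts(downSets)))
}

# mean log2fc across models, named by gene (genes assumed shared)
meanLog2fc <- function(perModelResults) {
  fc <- vapply(perModelResults, function(d) {
    setNames(d$log2fc, d$gene)[perModelResults[[1L]]$gene]
  }, numeric(nrow(perModelResults[[1L]])))
  rowMeans(fc)
}

#' Top signature genes by mean fold change
#'
#' Returns the first `n` genes of the signature's up-set ordered by
#' descending mean log2 fold change across models, ties broken
#' lexicographically by gene identifier.
#'
#' @param sig a [GeneSignature-class].
#' @param perModelResults the per-model DE results used to derive it.
#' @param n number of genes (capped at the up-set size, with a message).
#' @return data.frame `gene`, `meanLog2fc`, in rank order.
#' @export
topSignatureGenes <- function(sig, perModelResults, n = 20) {
  stopifnot(n >= 1)
  mfc <- meanLog2fc(perModelResults)[upGenes(sig)]
  if (n > length(mfc)) {
    message("n = ", n, " exceeds up-set size ", length(mfc),
            "; returning all")
    n <- length(mfc)
  }
  ord <- order(-mfc, names(mfc))
  data.frame(gene = names(mfc)[ord][seq_len(n)],
             meanLog2fc = unname(mfc[ord])[seq_len(n)], row.names = NULL)
}

#' Intersect a consensus signature with a treatment response
#'
#' Overlap between the consensus signature and the significant genes of a
#' treatment arm (e.g. interferon-treated vs control, tested at the same
#' thresholds), used to identify the treatment-shared part of the
#' signature.
#'
#' @param sig a [GeneSignature-class].
#' @param treatmentResults data.frame from [differentialExpression()] for
#'   the treatment contrast.
#' @return list with `up` and `down` overlap gene vectors (signature
#'   order preserved).
#' @export
intersectWithTreatment <- function(sig, treatmentResults) {
  list(up = intersect(upGenes(sig),
                      significantGenes(treatmentResults, "up")),
       down = intersect(downGenes(sig),
                        significantGenes(treatmentResults, "down")))
}

#' Write differential-expression results as CSV
#'
#' @param de data.frame from [differentialExpression()].
#' @param path output CSV path.
#' @export
writeDEResults <- function(de, path) {
  write.csv(de, path, row.names = FALSE)
  invisible(path)
}
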