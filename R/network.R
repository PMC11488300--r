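# Co-expression network by per-gene principal-component regression, virtual
# knockout, and diffusion-based perturbation ranking. This is a documented
# simplified variant of tensor-based knockout predictors: outputs carry a
# "pcnet-diffusion" method tag.

#' Build a gene-gene co-expression network by PC regression
#'
#' For each gene g, its (centered, unit-variance) expression across cells
#' is ridge-regressed on the top principal components of all other genes;
#' the PC coefficients are mapped back to per-gene weights and written as
#' row g of the adjacency matrix (row = regulated gene, columns =
#' regulators). Entries with |weight| below the sparsity quantile are
#' zeroed and the matrix is scaled so that max |weight| = 1. PC signs are
#' fixed by the largest-absolute-loading-positive convention, making the
#' network deterministic; cell order does not affect the result.
#'
#' @param x a `SingleCellExperiment` (the `logcounts` assay is used,
#'   computed via [normalizeLog()] if absent) or a plain genes x cells
#'   matrix of normalized log expression.
#' @param geneSubset genes to include; default the 500 most variable
#'   genes (all genes when fewer). At least 10 genes and 50 cells are
#'   required.
#' @param nPcs number of principal components per regression.
#' @param ridge ridge penalty added to the PC eigenvalues.
#' @param sparsityQuantile quantile of |weight| below which entries are
#'   zeroed.
#' @return A [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(x, geneSubset = NULL, nPcs = 5, ridge = 1.0,
                         sparsityQuantile = 0.95) {
  if (methods::is(x, "SingleCellExperiment")) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x)) {
      message("no logcounts assay; applying normalizeLog() defaults")
      x <- normalizeLog(x)
    }
    x <- as.matrix(SummarizedExperiment::assay(x, "logcounts"))
  }
  x <- as.matrix(x)
  if (is.null(geneSubset)) {
    v <- apply(x, 1L, var)
    geneSubset <- rownames(x)[order(-v, rownames(x))][
      seq_len(min(500L, nrow(x)))]
  }
  stopifnot(all(geneSubset %in% rownames(x)))
  x <- x[geneSubset, , drop = FALSE]
  p <- nrow(x); n <- ncol(x)
  if (p < 10L) stop("need >= 10 genes after subsetting")
  if (n < 50L) stop("need >= 50 cells")
  genes <- rownames(x)

  xs <- t(x)                              # cells x genes
  mu <- colMeans(xs)
  sdv <- apply(xs, 2L, sd)
  constant <- sdv == 0
  if (any(constant)) {
    warning(sum(constant), " constant gene(s); their rows/columns set to 0")
    sdv[constant] <- 1
  }
  xs <- sweep(sweep(xs, 2L, mu), 2L, sdv, `/`)
  xs[, constant] <- 0
  C <- crossprod(xs)

  W <- matrix(0, p, p, dimnames = list(genes, genes))
  k <- min(nPcs, p - 1L)
  for (g in seq_len(p)) {
    if (constant[g]) next
    Cg <- C[-g, -g, drop = FALSE]
    eg <- eigen(Cg, symmetric = TRUE)
    kk <- min(k, sum(eg$values > 1e-10))
    if (kk < 1L) next
    V <- eg$vectors[, seq_len(kk), drop = FALSE]
    for (j in seq_len(kk)) {              # sign convention
      i0 <- which.max(abs(V[, j]))
      if (V[i0, j] < 0) V[, j] <- -V[, j]
    }
    lam <- eg$values[seq_len(kk)]
    # scores T = X[,-g] V; with orthonormal V, T'T = diag(lam)
    ty <- crossprod(V, C[-g, g])
    beta <- as.numeric(ty) / (lam + ridge)
    W[g, -g] <- as.numeric(V %*% beta)
  }
  off <- W[row(W) != col(W)]
  thr <- quantile(abs(off), sparsityQuantile)
  W[abs(W) < thr] <- 0
  diag(W) <- 0
  mx <- max(abs(W))
  if (mx > 0) W <- W / mx
  new("CoexpressionNetwork", genes = genes, weights = W,
      nPcs = as.integer(k), sparsityQuantile = as.numeric(sparsityQuantile))
}

#' Virtual knockout of a gene
#'
#' Returns a copy of the network with the target's row and column zeroed,
#' removing both its incoming and outgoing influence. Idempotent.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param target gene identifier; unknown targets raise an error listing
#'   the nearest identifiers.
#' @return A [CoexpressionNetwork-class].
#' @export
knockout <- function(net, target) {
  genes <- netGenes(net)
  if (!target %in% genes) {
    near <- genes[order(utils::adist(target, genes))][seq_len(min(3L,
                                                                  length(genes)))]
    stop("unknown target '", target, "'; nearest identifiers: ",
         paste(near, collapse = ", "))
  }
  W <- netWeights(net)
  W[target, ] <- 0
  W[, target] <- 0
  methods::initialize(net, weights = W)
}

#' Rank genes perturbed by a knockout
#'
#' Propagates the difference between the intact and knocked-out networks
#' through a truncated diffusion operator
#' `S(A) = I + (alpha A) + (alpha A)^2 + ... + (alpha A)^horizon` and
#' scores every gene by the Euclidean distance between its rows of
#' `S(net)` and `S(netKo)`. Scores are therefore exactly zero outside the
#' `<= horizon`-step neighbourhood of the target. The robust z-score uses
#' the median and MAD over non-target genes; genes are ranked by
#' descending score (ties broken by gene identifier), with the target
#' reported but excluded from ranking.
#'
#' @param net,netKo intact and knocked-out networks over the same gene
#'   universe (see [knockout()]).
#' @param target the knocked-out gene; inferred from the zeroed row/column
#'   when omitted (identical networks then yield an all-zero profile with
#'   no excluded gene).
#' @param alpha diffusion damping in (0, 1); a warning is issued when
#'   `alpha * spectralRadius(net) >= 1`.
#' @param horizon maximum path length (>= 1).
#' @return A [PerturbationProfile-class].
#' @export
perturbationProfile <- function(net, netKo, target = NULL, alpha = 0.5,
                                horizon = 3) {
  stopifnot(identical(netGenes(net), netGenes(netKo)))
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 1L)
  A1 <- netWeights(net); A2 <- netWeights(netKo)
  if (is.null(target)) {
    nDiff <- rowSums(A1 != A2) + colSums(A1 != A2)
    target <- if (any(nDiff > 0)) netGenes(net)[which.max(nDiff)] else
      NA_character_
  } else {
    stopifnot(target %in% netGenes(net))
  }
  sr <- max(abs(eigen(A1, only.values = TRUE)$values))
  if (alpha * sr >= 1) {
    warning("alpha * spectral radius = ", signif(alpha * sr, 3),
            " >= 1; diffusion may be poorly damped")
  }
  S <- function(A) {
    P <- diag(nrow(A))
    out <- P
    for (t in seq_len(horizon)) {
      P <- P %*% (alpha * A)
      out <- out + P
    }
    out
  }
  D <- S(A1) - S(A2)
  score <- sqrt(rowSums(D^2))
  genes <- netGenes(net)
  names(score) <- genes
  ranked <- if (is.na(target)) seq_along(genes) else
    which(genes != target)
  others <- score[ranked]
  madv <- mad(others)
  z <- if (madv > 0) {
    (score - median(others)) / madv
  } else {
    rep(NA_real_, length(score))
  }
  ord <- order(-score[ranked], genes[ranked])
  rank <- rep(NA_integer_, length(score))
  rank[ranked[ord]] <- seq_along(ord)
  tab <- data.frame(gene = genes, score = unname(score), z = unname(z),
                    rank = rank, row.names = NULL)
  new("PerturbationProfile",
      target = if (is.na(target)) character() else target, table = tab,
      alpha = as.numeric(alpha), horizon = horizon,
      method = "pcnet-diffusion")
}

#' Export the top knockout-perturbed genes
#'
#' @param profile a [PerturbationProfile-class].
#' @param topN number of genes to report (truncated to the universe size
#'   with a warning; 0 gives an empty table).
#' @param file optional CSV path for the ranked table.
#' @param geneListFile optional path for a plain-text gene list (one gene
#'   per line, table order) for external enrichment tools.
#' @return data.frame `gene`, `score`, `z`, `rank` of the top genes.
#' @export
knockoutReport <- function(profile, topN = 50, file = NULL,
                           geneListFile = NULL) {
  tab <- profileTable(profile)
  tab <- tab[!is.na(tab$rank), , drop = FALSE]
  tab <- tab[order(tab$rank), , drop = FALSE]
  topN <- as.integer(topN)
  if (topN > nrow(tab)) {
    warning("topN = ", topN, " exceeds the ", nrow(tab),
            "-gene universe; truncated")
    topN <- nrow(tab)
  }
  out <- tab[seq_len(max(0L, topN)), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  if (!is.null(geneListFile)) writeLines(out$gene, geneListFile)
  out
}

#' Write a network as a sparse edge-list CSV
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path output CSV (`source`, `target`, `weight`; `target` is the
#'   regulated gene, i.e. the row).
#' @export
writeNetwork <- function(net, path) {
  W <- netWeights(net)
  idx <- which(W != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  df <- data.frame(source = netGenes(net)[idx[, "col"]],
                   target = netGenes(net)[idx[, "row"]],
                   weight = W[idx])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
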