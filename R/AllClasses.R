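#' @import methods
#' @importFrom stats cor kmeans mad median p.adjust pt quantile rbinom rlnorm
#'   rnbinom rnorm runif sd setNames var wilcox.test dnorm pbeta qbeta
#'   cor.test t.test
#' @importFrom utils read.csv read.delim write.csv write.table head
NULL

# ---------------------------------------------------------------------------
# GeneSignature
# ---------------------------------------------------------------------------

#' Gene signature: named up- and down-regulated gene sets
#'
#' A `GeneSignature` holds an ordered set of upregulated and (optionally)
#' downregulated gene identifiers, e.g. a consensus senescence signature
#' derived from several induction models. The two sets must be disjoint and
#' duplicate-free. Order is meaningful: signatures derived by
#' [deriveConsensus()] are ordered by mean log2 fold change.
#'
#' @slot name single character label.
#' @slot up character vector of upregulated gene identifiers.
#' @slot down character vector of downregulated gene identifiers.
#'
#' @seealso [deriveConsensus()], [readGMT()], [writeGMT()]
#' @export
setClass("GeneSignature",
  representation(name = "character", up = "character", down = "character"),
  prototype(name = "signature", up = character(), down = character())
)

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name)) {
    msg <- c(msg, "'name' must be a single non-NA string")
  }
  if (anyDuplicated(object@up)) msg <- c(msg, "duplicate genes in 'up'")
  if (anyDuplicated(object@down)) msg <- c(msg, "duplicate genes in 'down'")
  if (length(intersect(object@up, object@down)) > 0L) {
    msg <- c(msg, "'up' and 'down' sets must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param name signature label (used as the GMT record prefix).
#' @param up character vector of upregulated genes.
#' @param down character vector of downregulated genes (may be empty).
#' @return A [GeneSignature-class] object.
#' @examples
#' sig <- GeneSignature("demo", up = c("G1", "G2"), down = "G9")
#' upGenes(sig)
#' @export
GeneSignature <- function(name, up = character(), down = character()) {
  new("GeneSignature", name = as.character(name),
      up = as.character(up), down = as.character(down))
}

#' @describeIn GeneSignature signature label
#' @param x,object a `GeneSignature`
#' @export
sigName <- function(x) x@name

#' @describeIn GeneSignature upregulated gene identifiers
#' @export
upGenes <- function(x) x@up

#' @describeIn GeneSignature downregulated gene identifiers
#' @export
downGenes <- function(x) x@down

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "': ",
      length(object@up), " up / ", length(object@down), " down genes\n",
      sep = "")
  if (length(object@up)) {
    cat("  up:  ", paste(head(object@up, 5L), collapse = ", "),
        if (length(object@up) > 5L) ", ..." else "", "\n", sep = "")
  }
  if (length(object@down)) {
    cat("  down:", paste(head(object@down, 5L), collapse = ", "),
        if (length(object@down) > 5L) ", ..." else "", "\n", sep = "")
  }
})

# ---------------------------------------------------------------------------
# EnrichmentResult
# ---------------------------------------------------------------------------

#' Preranked GSEA result for one gene set on one ranked list
#'
#' Produced by [normalizedEnrichment()]. Holds the weighted running-sum
#' enrichment score (ES), the permutation-normalized score (NES, the ES
#' divided by the mean absolute null ES of the same sign), the one-sided
#' permutation p-value with +1 smoothing, and the leading-edge genes.
#'
#' @slot signatureName label of the scored gene set.
#' @slot es enrichment score in \[-1, 1\].
#' @slot nes normalized enrichment score (NA when no same-sign nulls exist).
#' @slot pPerm permutation p-value in (0, 1].
#' @slot nPerm number of gene-label permutations used for the null.
#' @slot leadingEdge gene-set members at or before (positive ES) / after
#'   (negative ES) the running-sum extremum.
#' @slot seed RNG seed used for the permutation null.
#' @export
setClass("EnrichmentResult",
  representation(signatureName = "character", es = "numeric", nes = "numeric",
                 pPerm = "numeric", nPerm = "integer",
                 leadingEdge = "character", seed = "integer")
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (abs(object@es) > 1 + 1e-12) msg <- c(msg, "|es| must be <= 1")
  if (!is.na(object@nes) && object@es != 0 &&
      sign(object@nes) != sign(object@es)) {
    msg <- c(msg, "sign(nes) must equal sign(es)")
  }
  if (object@pPerm <= 0 || object@pPerm > 1) {
    msg <- c(msg, "pPerm must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentResult enrichment score
#' @param x an `EnrichmentResult`
#' @export
esValue <- function(x) x@es

#' @describeIn EnrichmentResult normalized enrichment score
#' @export
nesValue <- function(x) x@nes

#' @describeIn EnrichmentResult permutation p-value
#' @export
pPerm <- function(x) x@pPerm

#' @describeIn EnrichmentResult leading-edge genes
#' @export
leadingEdge <- function(x) x@leadingEdge

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult for '", object@signatureName, "'\n",
      "  ES = ", signif(object@es, 4), ", NES = ", signif(object@nes, 4),
      ", p_perm = ", signif(object@pPerm, 4),
      " (", object@nPerm, " permutations)\n",
      "  leading edge: ", length(object@leadingEdge), " genes\n", sep = "")
})

# ---------------------------------------------------------------------------
# CoexpressionNetwork
# ---------------------------------------------------------------------------

#' Directed weighted gene-gene co-expression network
#'
#' Built by [buildNetwork()] via per-gene principal-component regression.
#' Row `g` holds the (sparsified, max-normalized) influence weights of all
#' other genes on gene `g`; the diagonal is zero.
#'
#' @slot genes ordered gene identifiers.
#' @slot weights dense numeric gene x gene matrix, diagonal 0, max |w| = 1
#'   after normalization (unless the matrix is all zero).
#' @slot nPcs number of principal components used per regression.
#' @slot sparsityQuantile quantile of |weight| below which entries were
#'   zeroed.
#' @export
setClass("CoexpressionNetwork",
  representation(genes = "character", weights = "matrix",
                 nPcs = "integer", sparsityQuantile = "numeric")
)

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  p <- length(object@genes)
  if (!all(dim(object@weights) == c(p, p))) {
    msg <- c(msg, "'weights' must be a square matrix matching 'genes'")
  } else {
    if (any(diag(object@weights) != 0)) msg <- c(msg, "diagonal must be 0")
    mx <- max(abs(object@weights))
    if (mx > 1 + 1e-8) msg <- c(msg, "max |weight| must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CoexpressionNetwork gene identifiers
#' @param x a `CoexpressionNetwork`
#' @export
netGenes <- function(x) x@genes

#' @describeIn CoexpressionNetwork weight matrix (row = regulated gene)
#' @export
netWeights <- function(x) x@weights

setMethod("show", "CoexpressionNetwork", function(object) {
  nz <- sum(object@weights != 0)
  cat("CoexpressionNetwork: ", length(object@genes), " genes, ",
      nz, " nonzero edges (", object@nPcs, " PCs, sparsity quantile ",
      object@sparsityQuantile, ")\n", sep = "")
})

# ---------------------------------------------------------------------------
# PerturbationProfile
# ---------------------------------------------------------------------------

#' Per-gene perturbation scores from a virtual knockout
#'
#' Produced by [perturbationProfile()]. Scores are Euclidean distances
#' between rows of the truncated diffusion operators of the intact and
#' knocked-out networks; the robust z uses the median/MAD over non-target
#' genes. The target's own score is reported but excluded from ranking.
#'
#' @slot target the knocked-out gene.
#' @slot table data.frame with columns `gene`, `score`, `z`, `rank`
#'   (rank is NA for the target).
#' @slot alpha diffusion damping factor.
#' @slot horizon maximum propagation path length.
#' @slot method method tag ("pcnet-diffusion").
#' @export
setClass("PerturbationProfile",
  representation(target = "character", table = "data.frame",
                 alpha = "numeric", horizon = "integer", method = "character")
)

setValidity("PerturbationProfile", function(object) {
  msg <- character()
  need <- c("gene", "score", "z", "rank")
  if (!all(need %in% names(object@table))) {
    msg <- c(msg, "table must have columns gene, score, z, rank")
  } else if (any(object@table$score < 0)) {
    msg <- c(msg, "scores must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PerturbationProfile full score table
#' @param x a `PerturbationProfile`
#' @export
profileTable <- function(x) x@table

#' @describeIn PerturbationProfile knocked-out gene
#' @export
targetGene <- function(x) x@target

setMethod("show", "PerturbationProfile", function(object) {
  tab <- object@table[!is.na(object@table$rank), , drop = FALSE]
  tab <- tab[order(tab$rank), , drop = FALSE]
  cat("PerturbationProfile (", object@method, "): target '", object@target,
      "', ", nrow(object@table) - 1L, " ranked genes\n", sep = "")
  cat("  top genes:", paste(head(tab$gene, 5L), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SenescenceCall
# ---------------------------------------------------------------------------

#' Binary senescence annotation of single cells
#'
#' Produced by [annotateSenescence()] from per-cell signature scores using a
#' two-component one-dimensional Gaussian mixture fitted by EM; the
#' component with the larger mean is labelled senescent. When the mixture
#' degenerates the method falls back to a median split.
#'
#' @slot posterior per-cell posterior probability of the senescent component.
#' @slot label per-cell logical senescent call (`posterior > 0.5`).
#' @slot mu component means (non-senescent, senescent).
#' @slot sigma component standard deviations.
#' @slot weight component mixing weights.
#' @slot groupFractions named per-group senescent fractions (empty when no
#'   groups were supplied).
#' @slot method "gmm-em" or "median-split".
#' @export
setClass("SenescenceCall",
  representation(posterior = "numeric", label = "logical", mu = "numeric",
                 sigma = "numeric", weight = "numeric",
                 groupFractions = "numeric", method = "character")
)

setValidity("SenescenceCall", function(object) {
  msg <- character()
  if (any(object@posterior < 0 | object@posterior > 1)) {
    msg <- c(msg, "posterior must lie in [0, 1]")
  }
  if (!identical(unname(object@label), unname(object@posterior > 0.5))) {
    msg <- c(msg, "label must equal posterior > 0.5")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SenescenceCall per-cell posterior probabilities
#' @param x a `SenescenceCall`
#' @export
posteriors <- function(x) x@posterior

#' @describeIn SenescenceCall per-cell logical senescent labels
#' @export
senescentLabels <- function(x) x@label

#' @describeIn SenescenceCall named per-group senescent fractions
#' @export
groupFractions <- function(x) x@groupFractions

setMethod("show", "SenescenceCall", function(object) {
  cat("SenescenceCall (", object@method, "): ", sum(object@label), "/",
      length(object@label), " cells senescent\n", sep = "")
  if (length(object@groupFractions)) {
    cat("  group fractions:\n")
    print(round(object@groupFractions, 3))
  }
})
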