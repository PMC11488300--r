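# RIP-qPCR quantification: percent-input normalization, delta-delta-Ct,
# and fold enrichment of an immunoprecipitated fraction over its
# nonspecific-antibody control.

#' Input-normalized delta-Ct
#'
#' Normalizes a RIP-fraction Ct to the input RNA fraction. The input Ct is
#' first shifted by `log2(dilutionFactor)` cycles to represent 100% input
#' (the standard percent-input adjustment: a 1% input corresponds to a
#' 100x dilution factor), then
#' `dCt = ctFraction - (ctInput - log2(dilutionFactor))`.
#'
#' @param ctFraction Ct of the RIP or nonspecific (NS) fraction.
#' @param ctInput Ct of the diluted input fraction.
#' @param dilutionFactor input dilution (default 100, i.e. 1% input);
#'   must be positive.
#' @return normalized delta-Ct (cycles). Vectorized.
#' @examples
#' normalizedDCt(25, 20, 100)  # 25 - (20 - log2(100)) = 11.644
#' @export
normalizedDCt <- function(ctFraction, ctInput, dilutionFactor = 100) {
  if (any(dilutionFactor <= 0)) stop("dilutionFactor must be > 0")
  if (!all(is.finite(ctFraction)) || !all(is.finite(ctInput))) {
    stop("Ct values must be finite")
  }
  ctFraction - (ctInput - log2(dilutionFactor))
}

#' Fold enrichment from normalized delta-Cts
#'
#' `ddCt = dCt(RIP) - dCt(NS)` and `fold = 2^(-ddCt)`: the abundance of
#' the target RNA in the specific immunoprecipitate relative to the
#' nonspecific-antibody control, both normalized to input.
#'
#' @param dctRip,dctNs normalized delta-Cts from [normalizedDCt()].
#' @return positive fold enrichment. Vectorized.
#' @examples
#' foldEnrichment(10, 10 + log2(10))  # 10-fold
#' @export
foldEnrichment <- function(dctRip, dctNs) {
  if (!all(is.finite(dctRip)) || !all(is.finite(dctNs))) {
    stop("delta-Ct values must be finite")
  }
  2^(-(dctRip - dctNs))
}

#' Fold-enrichment table from a raw Ct table
#'
#' Processes a long-format Ct table with columns `target`, `fraction`
#' (`RIP`, `NS`, or `input`), `antibody`, and `ct`. Technical replicates
#' are averaged per target x fraction before the delta-Ct computation
#' (set `aggregate = "none"` to pair replicates by their order within each
#' target x fraction instead and obtain per-replicate folds).
#'
#' @param ct data.frame as above (see [readCtTable()]).
#' @param dilutionFactor input dilution factor.
#' @param aggregate `"mean"` (default) or `"none"`.
#' @return data.frame with columns `target`, `antibody`, `dctRip`,
#'   `dctNs`, `ddct`, `fold` (one row per target, or per replicate when
#'   `aggregate = "none"`).
#' @export
ripFoldTable <- function(ct, dilutionFactor = 100,
                         aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  need <- c("target", "fraction", "antibody", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  badFrac <- setdiff(unique(ct$fraction), c("RIP", "NS", "input"))
  if (length(badFrac)) {
    stop("unknown fraction label(s): ", paste(badFrac, collapse = ", "))
  }
  rows <- lapply(unique(ct$target), function(tg) {
    sub <- ct[ct$target == tg, , drop = FALSE]
    getCt <- function(frac) sub$ct[sub$fraction == frac]
    ctIn <- getCt("input"); ctRip <- getCt("RIP"); ctNs <- getCt("NS")
    if (length(ctIn) == 0L || (length(ctRip) == 0L && length(ctNs) == 0L)) {
      stop("target '", tg, "' needs an input Ct and at least one of RIP/NS")
    }
    ab <- sub$antibody[sub$fraction == "RIP"][1L]
    if (is.na(ab)) ab <- sub$antibody[1L]
    if (aggregate == "mean") {
      ctIn <- mean(ctIn); ctRip <- mean(ctRip); ctNs <- mean(ctNs)
    } else {
      nrep <- max(length(ctRip), length(ctNs), length(ctIn))
      if (!all(c(length(ctRip), length(ctNs), length(ctIn)) %in%
               c(1L, nrep))) {
        stop("target '", tg, "': replicate counts do not align")
      }
    }
    dctRip <- normalizedDCt(ctRip, ctIn, dilutionFactor)
    dctNs <- normalizedDCt(ctNs, ctIn, dilutionFactor)
    data.frame(target = tg, antibody = ab, dctRip = dctRip, dctNs = dctNs,
               ddct = dctRip - dctNs,
               fold = foldEnrichment(dctRip, dctNs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a Ct table CSV
#'
#' @param path CSV with columns `target`, `fraction`, `antibody`, `ct`.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  ct <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "fraction", "antibody", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(ct$ct)) || any(ct$ct < 0)) {
    stop("Ct values must be finite and >= 0")
  }
  ct
}
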