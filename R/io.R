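# GMT and RNK readers/writers.

#' Read and write gene signatures in GMT format
#'
#' `writeGMT()` writes a signature as two GMT records, `<name>_up` and
#' (when the down-set is non-empty) `<name>_down`, with a free-text
#' description in the second column. `readGMT()` reads a GMT file back;
#' paired `*_up`/`*_down` records are merged into one
#' [GeneSignature-class], unpaired records become up-only signatures.
#'
#' @param sig a [GeneSignature-class].
#' @param path GMT file path.
#' @param description free-text second column.
#' @return `readGMT()` a named list of `GeneSignature` objects.
#' @export
writeGMT <- function(sig, path, description = "derived consensus signature") {
  lines <- character()
  if (length(upGenes(sig))) {
    lines <- c(lines, paste(c(paste0(sigName(sig), "_up"), description,
                              upGenes(sig)), collapse = "\t"))
  }
  if (length(downGenes(sig))) {
    lines <- c(lines, paste(c(paste0(sigName(sig), "_down"), description,
                              downGenes(sig)), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT record: ", f[1L])
    list(name = f[1L], genes = f[-(1:2)])
  })
  names(recs) <- vapply(recs, `[[`, character(1), "name")
  base <- sub("_(up|down)$", "", names(recs))
  out <- list()
  for (b in unique(base)) {
    members <- recs[base == b]
    up <- members[[paste0(b, "_up")]]$genes
    down <- members[[paste0(b, "_down")]]$genes
    if (is.null(up) && is.null(down)) {
      up <- members[[1L]]$genes
    }
    out[[b]] <- GeneSignature(b, up = if (is.null(up)) character() else up,
                              down = if (is.null(down)) character() else
                                down)
  }
  out
}

#' Write a ranked list as RNK
#'
#' @param ranked data.frame `gene`, `metric` from [rankGenes()].
#' @param path output path (gene TAB metric, no header).
#' @export
writeRNK <- function(ranked, path) {
  writeLines(sprintf("%s\t%.10g", ranked$gene, ranked$metric), path)
  invisible(path)
}
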