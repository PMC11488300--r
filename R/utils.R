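# Seed derivation and manifest helpers shared by the pipeline stages.

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global seed and a stage name to a 31-bit
#' integer seed, so pipeline stages (and benchmark cells) can be rerun
#' independently yet reproducibly.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @examples
#' stageSeed(1, "simulate") != stageSeed(1, "derive")
#' @export
stageSeed <- function(seed, stage) {
  m <- 2147483647                       # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(((as.numeric(seed) %% m) * 48271 + h) %% m)
}

# write a stage manifest: parameters, seed, package version and content
# hashes of every output file (no timestamps, so reruns are byte-identical)
writeManifest <- function(dir, stage, params, seed, files) {
  files <- files[file.exists(files)]
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", dir),
                    "/?"), "", files)
  manifest <- list(
    stage = stage,
    package = "senesig",
    version = as.character(utils::packageVersion("senesig")),
    seed = seed,
    parameters = params,
    files = lapply(setNames(seq_along(files), rel), function(i) {
      list(path = rel[i], md5 = unname(tools::md5sum(files[i])))
    })
  )
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
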