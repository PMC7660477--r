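#' Write a provenance record for a pipeline output
#'
#' Every analysis stage writes its results next to a small JSON block
#' recording the package version, the seed, and a digest of the options used,
#' so a rerun with the same seed and configuration is byte-identical.
#'
#' @param path output path of the JSON record.
#' @param seed seed used by the stage.
#' @param config list of options / configuration values (serialized as-is).
#' @param inputs character vector of input paths, if any.
#' @return the path, invisibly.
#' @export
write_provenance <- function(path, seed, config = list(), inputs = character()) {
  rec <- list(
    package = "maptrace",
    version = as.character(utils::packageVersion("maptrace")),
    seed = seed,
    config = config,
    inputs = inputs)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
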