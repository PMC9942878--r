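#' Record a reproducible run manifest
#'
#' The analysis drivers log, per stage, the parameters used, the effective
#' substream seeds, and MD5 checksums of every file written, so a rerun
#' with the same configuration can be verified byte-identical (timestamps
#' aside).
#'
#' @param stage stage name.
#' @param params list of stage parameters (must be JSON-serializable).
#' @param outputs character vector of file paths written by the stage.
#' @param manifest_path JSON file to create or extend.
#' @return the manifest list, invisibly.
#' @export
record_manifest <- function(stage, params, outputs, manifest_path) {
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else list()
  sums <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
  manifest[[stage]] <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("ampliscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    output_md5 = sums)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
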