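#' Write a machine-readable run manifest
#'
#' Records inputs, parameter values, seed, package version and md5
#' checksums of the produced outputs, sufficient to re-run the result.
#'
#' @param path output JSON path.
#' @param subcommand name of the pipeline stage.
#' @param inputs character vector of input paths.
#' @param params named list of parameter values.
#' @param outputs character vector of output paths (checksummed).
#' @param seed RNG seed used (or NULL).
#' @export
write_run_manifest <- function(path, subcommand, inputs, params, outputs,
                               seed = NULL) {
  sums <- tools::md5sum(outputs[file.exists(outputs)])
  manifest <- list(
    subcommand = subcommand,
    package = "nomeclone",
    version = as.character(utils::packageVersion("nomeclone")),
    seed = seed,
    inputs = as.list(inputs),
    params = params,
    outputs = lapply(seq_along(sums), function(i) {
      list(path = names(sums)[i], md5 = unname(sums[i]))
    }))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
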