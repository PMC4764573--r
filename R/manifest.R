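# Run bookkeeping: a small manifest that records everything needed to
# reproduce a deterministic pipeline stage bit-for-bit.

#' Record a run manifest
#'
#' Writes a YAML manifest (stage name, configuration path, input and output
#' paths, seed, package version, timestamp) next to a stage's outputs. The
#' recorded seed and paths suffice to reproduce deterministic stages exactly.
#'
#' @param stage stage name (e.g. `"simulate"`, `"quantify"`).
#' @param out_dir output directory; the manifest is written there as
#'   `manifest_<stage>.yaml`.
#' @param seed integer seed used by the stage.
#' @param config_path path of the configuration file, if any.
#' @param inputs named character vector of input paths.
#' @param outputs named character vector of output paths.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(stage, out_dir, seed = NA_integer_,
                               config_path = NULL, inputs = character(),
                               outputs = character()) {
  manifest <- list(
    stage = stage,
    config = config_path,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    seed = seed,
    tool_version = as.character(utils::packageVersion("exportome")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(manifest, file.path(out_dir,
                                       sprintf("manifest_%s.yaml", stage)))
  invisible(manifest)
}
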