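#' Write a run manifest next to an analysis artifact
#'
#' Every analysis driver records what produced its outputs: the command
#' label, the configuration actually used, the seed, input file digests
#' and the output paths. Deterministic stages are bit-reproducible from
#' the manifest alone.
#'
#' @param path manifest file path (JSON).
#' @param command short label of the producing step.
#' @param config list of configuration values (serialized as-is).
#' @param seed integer seed used, if any.
#' @param inputs character vector of input file paths (digested by size).
#' @param outputs character vector of produced file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NULL,
                               inputs = character(0), outputs = character(0)) {
  digest <- function(files) {
    if (!length(files)) return(list())
    stats::setNames(lapply(files, function(f) {
      list(exists = file.exists(f),
           bytes = if (file.exists(f)) file.size(f) else NA)
    }), files)
  }
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = digest(inputs),
    outputs = as.list(outputs),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Interim-report warning banner
#'
#' The text pattern a live monitoring report carries so that interim
#' Bayes-factor trajectories are not over-interpreted before a
#' pre-specified stopping point.
#'
#' @param next_point the next analysis point (cumulative erotic trials).
#' @return character scalar.
#' @export
interim_warning_banner <- function(next_point) {
  paste0("Result not yet final! Data presented here represent the current ",
         "trend calculated from the data. Random variations may cause the ",
         "data to cross the decision thresholds. Statistical decisions will ",
         "only be drawn at the pre-specified stopping points. The next ",
         "stopping point will be at reaching ", next_point, " trials.")
}
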