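# recognised pipeline stages and their parameter requirements
.RUN_COMMANDS <- c("design", "predict", "nucleation", "grow", "render", "analyze")
.STOCHASTIC_COMMANDS <- c("grow", "render")
.RUN_CONFIG_KEYS <- c("command", "params", "output_dir", "rng_seed", "log_level")

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML (or JSON) configuration with keys `command` (one of design,
#' predict, nucleation, grow, render, analyze), `params` (stage-specific
#' block), `output_dir`, `rng_seed` and optional `log_level`. Stochastic
#' commands (`grow`, `render`) require `rng_seed`.
#'
#' @param path Path to the config file.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(raw)
}

#' Validate a run configuration
#'
#' @param config A named list.
#' @return The config with class `run_config`; errors list every offending
#'   key.
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  unknown <- setdiff(names(config), .RUN_CONFIG_KEYS)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  if (is.null(config$command) || !config$command %in% .RUN_COMMANDS)
    problems <- c(problems, paste0("command must be one of: ",
                                   paste(.RUN_COMMANDS, collapse = ", ")))
  if (!is.null(config$command) && config$command %in% .STOCHASTIC_COMMANDS &&
      is.null(config$rng_seed))
    problems <- c(problems, paste0("rng_seed is required for command '",
                                   config$command, "'"))
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(config, class = "run_config")
}

#' Write a run manifest
#'
#' Records the effective configuration, package version and produced
#' artifacts so a run can be reproduced exactly; [load_run_config()] on a
#' manifest restores the same effective configuration.
#'
#' @param config A `run_config`.
#' @param outputs Character vector of artifact paths written by the run.
#' @param path Manifest output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, outputs, path) {
  stopifnot(inherits(config, "run_config"))
  rec <- unclass(config)
  rec$.manifest <- list(
    package = "dnamoire",
    version = as.character(utils::packageVersion("dnamoire")),
    outputs = as.character(outputs))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load the effective configuration back from a manifest
#'
#' @param path A manifest written by [write_manifest()].
#' @return The validated `run_config` it records.
#' @export
load_manifest_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$.manifest <- NULL
  validate_run_config(raw)
}

#' Write nucleation curves as CSV
#'
#' @param curves A `nucleation_curves` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  utils::write.csv(as.data.frame(curves), path, row.names = FALSE)
  invisible(path)
}
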