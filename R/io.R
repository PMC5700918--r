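#' Read and write the package's CSV dialects
#'
#' Tidy CSV round-trip for bioassay tables (columns `block`, `strain`,
#' `variety`, `interval_h`, `released`, `on_fed`, `on_notfed`, `off_fed`,
#' `off_notfed`, `unrecovered`) and track tables (columns `strain`,
#' `variety`, `distance_cm`, `velocity_cm_s`, `mobility_s`). Readers
#' validate the schema; the bioassay reader also enforces count
#' conservation and reports offending row numbers.
#'
#' @param records,tracks data.frames to write.
#' @param path file path.
#' @return readers return the validated data.frame; writers return `path`
#'   invisibly.
#' @name spodsim_csv
NULL

#' @rdname spodsim_csv
#' @export
write_bioassay_csv <- function(records, path) {
  validate_bioassay(records)
  cols <- c("block", "strain", "variety", "interval_h", "released",
            "on_fed", "on_notfed", "off_fed", "off_notfed", "unrecovered")
  if (!"block" %in% names(records)) records$block <- NA_integer_
  write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spodsim_csv
#' @export
read_bioassay_csv <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  records <- read.csv(path, stringsAsFactors = FALSE)
  validate_bioassay(records)
  records
}

#' @rdname spodsim_csv
#' @export
write_tracks_csv <- function(tracks, path) {
  cols <- c("strain", "variety", "distance_cm", "velocity_cm_s",
            "mobility_s")
  missing <- setdiff(cols, names(tracks))
  if (length(missing))
    abort("track table missing columns: ", paste(missing, collapse = ", "))
  write.csv(tracks[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname spodsim_csv
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  tracks <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("strain", "variety", "distance_cm", "velocity_cm_s",
            "mobility_s")
  missing <- setdiff(cols, names(tracks))
  if (length(missing))
    abort("track CSV missing columns: ", paste(missing, collapse = ", "))
  if (any(as.matrix(tracks[cols[3:5]]) < 0))
    abort("track endpoints must be >= 0")
  tracks
}

#' Read a run configuration file
#'
#' Configurations are plain `key: value` text (a YAML mapping), mirroring
#' the arguments of [bioassay_design()], [bioassay_params()] and
#' [scenario_config()]. Unknown keys are an error so typos do not silently
#' fall back to defaults.
#'
#' @param path config file path.
#' @param allowed optional character vector of allowed keys.
#' @return named list of configuration values.
#' @export
read_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) abort("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a key: value mapping")
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown))
      abort("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Write a run manifest
#'
#' Records what a command run produced: the command name, the
#' configuration snapshot, the master seed, the package version, a
#' timestamp and the output file list, as JSON. Re-running the command
#' with the manifest's config and seed reproduces the CSV payloads
#' byte-identically.
#'
#' @param path manifest path (JSON).
#' @param command command name.
#' @param config configuration list snapshot.
#' @param seed master seed used.
#' @param outputs character vector of files written.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config, seed, outputs) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package = "spodsim",
    version = as.character(packageVersion("spodsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
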