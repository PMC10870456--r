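#' Write a COP trial to CSV plus a JSON sidecar
#'
#' The trial format is a CSV with header `time_s,cop_ap_cm,cop_ml_cm`
#' (values serialized with 9 significant digits) and a JSON sidecar of the
#' same basename holding `target_onset_s`, `sampling_hz`, `target_id` and
#' the free-form metadata. Writing then reading reproduces the trial to
#' the serialized precision; re-serializing the read trial is bit-stable.
#'
#' @param trial a [cop_trial].
#' @param path path of the CSV file (`.csv`); the sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  df <- data.frame(time_s = sprintf("%.9g", trial$time + 0),
                   cop_ap_cm = sprintf("%.9g", trial$cop_ap + 0),
                   cop_ml_cm = sprintf("%.9g", trial$cop_ml + 0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(target_onset_s = trial$target_onset,
                  sampling_hz = trial$sampling_hz,
                  target_id = trial$target_id,
                  metadata = trial$metadata)
  # drop the bulky internal-state diagnostics from the on-disk format
  sidecar$metadata$states <- NULL
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a COP trial written by [write_trial()]
#'
#' @param path path of the CSV file; the JSON sidecar must sit next to it.
#' @return A [cop_trial].
#' @export
read_trial <- function(path) {
  sidecar_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    ls_abort(sprintf("trial files not found: %s (+ .json sidecar)", path),
             "leansim_error_format")
  }
  df <- read.csv(path)
  need <- c("time_s", "cop_ap_cm", "cop_ml_cm")
  if (!identical(names(df), need)) {
    ls_abort(sprintf("trial CSV must have header %s",
                     paste(need, collapse = ",")), "leansim_error_format")
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("target_onset_s", "sampling_hz", "target_id")) {
    if (is.null(sc[[key]])) {
      ls_abort(sprintf("sidecar is missing required key `%s`", key),
               "leansim_error_format", field = key)
    }
  }
  inferred_hz <- 1 / median(diff(df$time_s))
  if (abs(inferred_hz - sc$sampling_hz) > 1e-3 * sc$sampling_hz) {
    ls_abort(sprintf(
      "sidecar sampling_hz (%g) disagrees with the time grid (%g Hz)",
      sc$sampling_hz, inferred_hz), "leansim_error_format",
      field = "sampling_hz")
  }
  md <- sc$metadata
  if (is.null(md)) md <- list()
  cop_trial(time = df$time_s, cop_ap = df$cop_ap_cm, cop_ml = df$cop_ml_cm,
            target_onset = sc$target_onset_s, target_id = sc$target_id,
            sampling_hz = sc$sampling_hz, metadata = md)
}

#' Write a delimited results table with provenance header
#'
#' All pipeline outputs are tab-separated tables prefixed with a comment
#' line carrying the configuration hash and seed of the run, so any table
#' can be traced back to the exact settings that produced it.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param config_hash,seed provenance fields (optional).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path, config_hash = NA, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# leansim\tconfig_hash=%s\tseed=%s",
                     config_hash, seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path input path.
#' @return A data.frame; the provenance line is exposed as attribute
#'   `provenance`.
#' @export
read_results_table <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "#")) attr(df, "provenance") <- first
  df
}

.config_sections <- c("anthropometry", "plant", "planning", "control",
                      "simulation", "segmentation", "identification",
                      "cohort", "pipeline", "seed", "paths", "log_level")

#' Read and validate a run configuration (JSON)
#'
#' The run configuration is a JSON object whose top-level sections mirror
#' the package's configuration constructors (`simulation` ->
#' [sim_config()], `segmentation` -> [segment_config()], ...). Unknown
#' top-level keys are rejected so typos fail loudly.
#'
#' @param path path of the JSON file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    ls_abort(sprintf("config file not found: %s", path),
             "leansim_error_config")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_sections)
  if (length(unknown) > 0) {
    ls_abort(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")),
             "leansim_error_config", keys = unknown)
  }
  if (!is.null(cfg$seed)) check_number(cfg$seed, "seed")
  structure(cfg, class = c("run_config", class(cfg)))
}

#' Canonical hash of a configuration
#'
#' MD5 of the canonical JSON serialization; used as the provenance tag on
#' every output table.
#'
#' @param cfg a configuration list.
#' @return A character MD5 digest.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = 15)
  unname(tools::md5sum(tmp))
}

#' Serialize a run configuration back to JSON
#'
#' `write_run_config()` then [read_run_config()] is idempotent.
#'
#' @param cfg a configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = 15,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export a target layout as a delimited table
#'
#' @param layout a [target_layout].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  write_results_table(as.data.frame(layout), path)
}
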