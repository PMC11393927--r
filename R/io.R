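# Configuration loading and report writing.

config_defaults <- function() {
  c(as.list(unclass(staircase_config())),
    list(seed = NULL, language = "de", verbosity = 1L))
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration (chosen from the file extension),
#' validates it and applies the protocol defaults (3-letter pseudowords at
#' 250 ms, 50 ms steps up to 500 ms, 20-item lists, 95% criterion). Unknown
#' keys are rejected by name.
#'
#' @param path config file path; an empty file yields the full defaults.
#' @return a validated named list (`run_config`): the [staircase_config()]
#'   fields plus `seed`, `language`, `verbosity`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_precondition("config file not found: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  user <- user %||% list()
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_precondition("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  # staircase_config re-validates the protocol fields (ranges, grid)
  sc <- staircase_config(cfg$start_length, cfg$start_time_ms, cfg$time_step_ms,
                         cfg$max_time_ms, cfg$list_size, cfg$pass_fraction,
                         cfg$max_length, cfg$vrt_grid_ms)
  out <- c(as.list(unclass(sc)),
           list(seed = cfg$seed, language = cfg$language,
                verbosity = cfg$verbosity))
  structure(out, class = "run_config")
}

#' Write a run configuration
#'
#' @param config a `run_config` (or plain named list of config fields).
#' @param path output path (`.yaml`/`.yml` for YAML, otherwise JSON).
#' @return `path`, invisibly.
#' @rdname load_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

report_schema_version <- "1"

result_to_list <- function(x) {
  if (inherits(x, "diagnostic_result")) {
    list(kind = "diagnostic_result",
         capacity_estimate = as.list(x$capacity_estimate),
         min_time_for_length = as.list(x$min_time_for_length),
         vrt_estimate_ms = x$vrt_estimate_ms,
         causes = as.list(x$causes))
  } else if (inherits(x, "causal_classification")) {
    list(kind = "causal_classification",
         gamma = as.list(x$gamma),
         lambda_sets = lapply(x$lambda_sets, as.list),
         superfluous = as.list(x$superfluous),
         canonical = x$canonical,
         witness = if (is.null(x$witness)) NULL else as.list(x$witness))
  } else if (inherits(x, "therapy_outcome")) {
    list(kind = "therapy_outcome",
         errors_unguided = x$errors_unguided,
         errors_guided = x$errors_guided,
         reduction_percent = x$reduction_percent,
         hedges_g = x$hedges_g)
  } else if (inherits(x, "segment_plan")) {
    list(kind = "segment_plan",
         coordinates = "letters-only stream, 0-based, half-open",
         capacity = x$capacity,
         segments = lapply(seq_len(nrow(x$segments)), function(i)
           as.list(x$segments[i, c("start", "end", "text", "word")])),
         fixation_targets = x$fixation_targets,
         amplitudes = x$amplitudes)
  } else {
    stop_precondition("write_report does not know how to serialize a ",
                      paste(class(x), collapse = "/"), " object")
  }
}

#' Write machine- and human-readable reports
#'
#' Writes `<path>.json` (full precision, with a `schema_version` field) and
#' `<path>.md` (a short human summary) for any of the package's result
#' objects. Diagnostic results additionally write their trial log to
#' `<path>_trials.csv`; therapy outcomes write the per-reader table to
#' `<path>_readers.csv`.
#'
#' @param result a `diagnostic_result`, `causal_classification`,
#'   `therapy_outcome` or `segment_plan`.
#' @param path output path prefix (no extension).
#' @param seed optional seed to embed in the report metadata.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(result, path, seed = NULL) {
  body <- result_to_list(result)
  body$schema_version <- report_schema_version
  if (!is.null(seed)) body$seed <- seed
  json_path <- paste0(path, ".json")
  jsonlite::write_json(body, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  md_path <- paste0(path, ".md")
  con <- file(md_path, "w")
  sink(con); print(result); sink()
  close(con)
  written <- c(json_path, md_path)
  if (inherits(result, "diagnostic_result")) {
    csv <- paste0(path, "_trials.csv")
    utils::write.csv(result$trial_log[, c("phase", "item", "presentation_ms",
                                          "allowed_vrt_ms", "correct")],
                     csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (inherits(result, "therapy_outcome")) {
    csv <- paste0(path, "_readers.csv")
    utils::write.csv(result$per_reader, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  invisible(written)
}
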