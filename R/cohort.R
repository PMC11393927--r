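# Synthetic cohorts of virtual readers.
#
# The sampler emulates the study populations of the pseudoword experiments:
# per-child ceilings of 3-6 simultaneously recognizable letters (6 being
# rare), capacity that grows with fixation time on the 50 ms grid up to
# 500 ms, and verbal reaction times from a positive-truncated normal with the
# two reported presets (mean 1316, SD 712 vs mean 1670, SD 641).

# Inverse-CDF sampler for a normal truncated below at `lower`.
rtruncated_normal <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, p0, 1))
}

# Analytic mean of the same truncated normal (used by tests and reported
# alongside cohort summaries).
truncated_normal_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

vrt_presets <- list(
  low_vrt  = list(mean = 1316, sd = 712),
  high_vrt = list(mean = 1670, sd = 641)
)

#' Sample a synthetic cohort of readers
#'
#' Draws `n` virtual readers. Letter-capacity ceilings are drawn from
#' \{3, 4, 5, 6\} with probabilities (0.3, 0.3, 0.3, 0.1); each reader reaches
#' their ceiling at a threshold time drawn uniformly from \{350, 400, 450,
#' 500\} ms, below which capacity falls by one letter per 50 ms step (never
#' below 3, the shortest pseudoword length used diagnostically). Required
#' verbal reaction times are drawn from a normal truncated below at 200 ms
#' (a physiological floor), with preset `low_vrt` = N(1316, 712^2) or
#' `high_vrt` = N(1670, 641^2). All readers get the whole-word strategy,
#' compliance 0.9 and lapse rate 0.02.
#'
#' @param n number of readers (>= 1).
#' @param preset `"low_vrt"` or `"high_vrt"`.
#' @param rng_seed optional integer seed.
#' @return list of [reader_profile()] objects.
#' @examples
#' cohort <- sample_cohort(5, "low_vrt", rng_seed = 1)
#' sapply(cohort, function(r) r$required_vrt_ms)
#' @export
sample_cohort <- function(n, preset = c("low_vrt", "high_vrt"), rng_seed = NULL) {
  preset <- match.arg(preset)
  if (!is_count(n)) stop_precondition("n must be a positive integer")
  p <- vrt_presets[[preset]]
  with_seed(rng_seed, {
    ceilings <- sample(c(3L, 4L, 5L, 6L), n, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1))
    thresholds <- sample(seq(350, 500, by = 50), n, replace = TRUE)
    vrts <- rtruncated_normal(n, p$mean, p$sd, lower = 200)
    lapply(seq_len(n), function(i) {
      grid <- seq(250, 500, by = 50)
      caps <- pmin(ceilings[i],
                   pmax(3L, ceilings[i] - (thresholds[i] - grid) %/% 50L))
      reader_profile(
        capacity_by_time = stats::setNames(as.integer(caps), grid),
        required_vrt_ms = vrts[i],
        lapse_rate = 0.02,
        strategy = "whole_word",
        compliance = 0.9
      )
    })
  })
}

# ---- serialization ---------------------------------------------------------

profile_to_list <- function(reader) {
  list(
    capacity_by_time = as.list(stats::setNames(
      as.integer(reader$capacity_by_time), names(reader$capacity_by_time))),
    required_vrt_ms = reader$required_vrt_ms,
    lapse_rate = reader$lapse_rate,
    strategy = reader$strategy,
    field_defect = if (is.null(reader$field_defect)) NULL else
      list(side = reader$field_defect$side,
           foveal_involvement = reader$field_defect$foveal_involvement,
           compensation = reader$field_defect$compensation),
    compliance = reader$compliance,
    grapheme_confusions = as.list(reader$grapheme_confusions)
  )
}

profile_from_list <- function(x) {
  fd <- NULL
  if (!is.null(x$field_defect))
    fd <- visual_field_defect(x$field_defect$side,
                              isTRUE(x$field_defect$foveal_involvement),
                              x$field_defect$compensation)
  reader_profile(
    capacity_by_time = unlist(x$capacity_by_time),
    required_vrt_ms = x$required_vrt_ms,
    lapse_rate = x$lapse_rate %||% 0,
    strategy = x$strategy %||% "whole_word",
    field_defect = fd,
    compliance = x$compliance %||% 1,
    grapheme_confusions = unlist(x$grapheme_confusions) %||% character()
  )
}

#' Read and write reader profiles
#'
#' Profiles serialize to JSON or YAML (chosen from the file extension; `.yml`
#' and `.yaml` are YAML, anything else JSON) with keys matching the
#' [reader_profile()] field names. Cohorts serialize to JSON Lines, one
#' profile per line.
#'
#' @param reader a [reader_profile()]; `cohort` a list of them.
#' @param path file path.
#' @return `read_profile()` a [reader_profile()]; `read_cohort()` a list of
#'   them; the writers return `path` invisibly.
#' @export
write_profile <- function(reader, path) {
  stopifnot(inherits(reader, "reader_profile"))
  x <- profile_to_list(reader)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  profile_from_list(x)
}

#' @rdname write_profile
#' @param cohort list of [reader_profile()] objects.
#' @export
write_cohort <- function(cohort, path) {
  lines <- vapply(cohort, function(r) {
    jsonlite::toJSON(profile_to_list(r), auto_unbox = TRUE, digits = NA,
                     null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) profile_from_list(jsonlite::fromJSON(l, simplifyVector = FALSE)))
}
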