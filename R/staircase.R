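#' Staircase protocol configuration
#'
#' Defaults follow the tachistoscopic pseudoword protocol: lists of 20
#' pseudowords, starting at 3 letters presented for 250 ms, fixation time
#' escalated in 50 ms steps up to 500 ms, pass criterion 95% of the list
#' correct, and a 50 ms grid for the verbal-reaction-time bisection.
#'
#' @param start_length first pseudoword length administered.
#' @param start_time_ms first presentation time (ms).
#' @param time_step_ms escalation step (ms).
#' @param max_time_ms largest presentation time (ms); must be reachable from
#'   `start_time_ms` in whole steps.
#' @param list_size items per list.
#' @param pass_fraction fraction of a list that must be read correctly.
#' @param max_length largest pseudoword length administered.
#' @param vrt_grid_ms grid (ms) on which the minimal allowed VRT is resolved.
#' @return a `staircase_config` list.
#' @export
staircase_config <- function(start_length = 3L, start_time_ms = 250L,
                             time_step_ms = 50L, max_time_ms = 500L,
                             list_size = 20L, pass_fraction = 0.95,
                             max_length = 8L, vrt_grid_ms = 50L) {
  cfg <- list(start_length = as.integer(start_length),
              start_time_ms = as.integer(start_time_ms),
              time_step_ms = as.integer(time_step_ms),
              max_time_ms = as.integer(max_time_ms),
              list_size = as.integer(list_size),
              pass_fraction = as.numeric(pass_fraction),
              max_length = as.integer(max_length),
              vrt_grid_ms = as.integer(vrt_grid_ms))
  if ((cfg$max_time_ms - cfg$start_time_ms) %% cfg$time_step_ms != 0L)
    stop_precondition("start_time_ms + k * time_step_ms must reach max_time_ms exactly")
  if (!(cfg$pass_fraction > 0 && cfg$pass_fraction <= 1))
    stop_precondition("pass_fraction must lie in (0, 1]")
  if (cfg$start_length < 1L || cfg$max_length < cfg$start_length)
    stop_precondition("need 1 <= start_length <= max_length")
  structure(cfg, class = "staircase_config")
}

#' List pass criterion
#'
#' A list passes iff at least `ceiling(pass_fraction * list_size)` items were
#' read correctly; with the defaults that is 19 of 20 (the 95% criterion).
#'
#' @param correct_count number of items read correctly.
#' @param list_size items in the list.
#' @param pass_fraction required fraction.
#' @return logical.
#' @examples
#' list_criterion(19, 20, 0.95)  # TRUE
#' list_criterion(18, 20, 0.95)  # FALSE
#' @export
list_criterion <- function(correct_count, list_size = 20L, pass_fraction = 0.95) {
  if (!is_count(correct_count, 0L) || correct_count > list_size)
    stop_precondition("need 0 <= correct_count <= list_size")
  correct_count >= ceiling(pass_fraction * list_size)
}

# Wrap a responder (a reader_profile or a list(respond=, spell=)) into the
# two functions the protocol needs. For simulated readers the spelling probe
# is ground truth: the item was visually recognized iff it fits the capacity
# at the current presentation time and the whole window was seen.
as_responder <- function(responder) {
  if (inherits(responder, "reader_profile")) {
    reader <- responder
    list(
      respond = function(item, presentation_ms, allowed_vrt_ms) {
        recognize(reader, item, presentation_ms, allowed_vrt_ms)$correct
      },
      spell = function(item, presentation_ms) {
        len <- length(letters_only(item))
        fix <- (len - 1L) %/% 2L
        len <= capacity_at(reader, presentation_ms) &&
          length(visible_window(len, fix, reader$field_defect)) == len
      }
    )
  } else if (is.list(responder) && is.function(responder$respond) &&
             is.function(responder$spell)) {
    responder
  } else {
    stop_precondition("responder must be a reader_profile or a list(respond=, spell=)")
  }
}

#' Run the adaptive tachistoscopic staircase
#'
#' Recovers a reader's letter capacity at each fixation time, the minimal
#' fixation time per pseudoword length, and the minimal allowed verbal
#' reaction time (VRT), then attributes causes of reading failure.
#'
#' Protocol: lists of `list_size` pseudowords are administered at the current
#' (length, time) with a generous allowed VRT (`max_time_ms` + 3000 ms, so
#' the VRT never confounds capacity estimation). A passing list escalates the
#' length; a failing list triggers a spelling probe on a missed item. If the
#' item was not visually recognized the failure is a capacity/fixation-time
#' limit and the fixation time escalates by `time_step_ms` (same length); if
#' it was visually recognized while the allowed VRT was generous, the failure
#' can only be a lapse streak and up to two fresh lists are administered at
#' the same cell. The sweep terminates when a length fails at `max_time_ms`
#' or `max_length` passes. Finally the minimal allowed VRT is bisected on the
#' `vrt_grid_ms` grid at the reader's best (length, time).
#'
#' @param responder a [reader_profile()] (simulated) or a
#'   `list(respond = function(item, presentation_ms, allowed_vrt_ms),
#'   spell = function(item, presentation_ms))` for external responders.
#' @param items_fn pseudoword source `(item_length, n) -> character(n)`;
#'   defaults to [pseudoword_source()] over the bundled lexicon.
#' @param config a [staircase_config()].
#' @param rng_seed optional integer seed governing item choice and the
#'   responder's stochastic behaviour.
#' @return A `diagnostic_result` with fields `capacity_estimate` (time ->
#'   max passing length; `NA` where nothing at or above `start_length`
#'   passed), `min_time_for_length`, `vrt_estimate_ms`, `trial_log`
#'   (data.frame: phase, item, presentation_ms, allowed_vrt_ms, correct) and
#'   `causes`.
#' @examples
#' r <- reader_profile(c(`250` = 3, `300` = 4, `350` = 4, `400` = 5,
#'                       `450` = 5, `500` = 6), required_vrt_ms = 1400)
#' d <- run_staircase(r, rng_seed = 1)
#' d$capacity_estimate
#' @export
run_staircase <- function(responder, items_fn = NULL,
                          config = staircase_config(), rng_seed = NULL) {
  stopifnot(inherits(config, "staircase_config"))
  resp <- as_responder(responder)
  with_seed(rng_seed, {
    if (is.null(items_fn)) items_fn <- pseudoword_source()
    generous <- config$max_time_ms + 3000L
    times_grid <- seq(config$start_time_ms, config$max_time_ms,
                      by = config$time_step_ms)

    log <- list()
    administer <- function(len, time_ms, allowed, phase) {
      items <- items_fn(len, config$list_size)
      ok <- vapply(items, function(it) isTRUE(resp$respond(it, time_ms, allowed)),
                   logical(1), USE.NAMES = FALSE)
      log[[length(log) + 1L]] <<- data.frame(
        phase = phase, item = items, presentation_ms = time_ms,
        allowed_vrt_ms = allowed, correct = ok)
      list(pass = list_criterion(sum(ok), config$list_size, config$pass_fraction),
           failed_items = items[!ok])
    }

    max_pass <- stats::setNames(rep(NA_integer_, length(times_grid)),
                                times_grid)
    len <- config$start_length
    t_ms <- config$start_time_ms
    phase <- "length_sweep"
    lapse_retries <- 0L

    repeat {
      res <- administer(len, t_ms, generous, phase)
      if (res$pass) {
        ti <- as.character(t_ms)
        max_pass[ti] <- max(max_pass[ti], len, na.rm = TRUE)
        lapse_retries <- 0L
        if (len >= config$max_length) break
        len <- len + 1L
        phase <- "length_sweep"
      } else {
        probe_item <- res$failed_items[[1L]]
        visually_ok <- isTRUE(resp$spell(probe_item, t_ms))
        log[[length(log) + 1L]] <- data.frame(
          phase = "spell_check", item = probe_item, presentation_ms = t_ms,
          allowed_vrt_ms = generous, correct = visually_ok)
        if (visually_ok) {
          # Allowed VRT is generous here, so a visually recognized miss can
          # only be a lapse streak: retry the cell with fresh items.
          if (lapse_retries < 2L) {
            lapse_retries <- lapse_retries + 1L
            next
          }
          break  # persistent unexplained failure: stop the sweep
        }
        lapse_retries <- 0L
        if (t_ms < config$max_time_ms) {
          t_ms <- t_ms + config$time_step_ms
          phase <- "time_sweep"
        } else {
          break  # length fails at max_time: capacity limit reached
        }
      }
    }

    # Monotone fill: the estimate at time t is the best length passed at any
    # time <= t (capacity is non-decreasing in time, and every grid time up
    # to the termination time was visited).
    capacity_estimate <- max_pass
    best <- NA_integer_
    for (i in seq_along(times_grid)) {
      ti <- as.character(times_grid[i])
      if (!is.na(max_pass[ti])) best <- max(best, max_pass[ti], na.rm = TRUE)
      capacity_estimate[ti] <- best
    }
    # (If max_length passed at time t*, the fill above already carries that
    # value to all later, unvisited grid times.)

    ceiling_est <- if (all(is.na(capacity_estimate))) NA_integer_ else
      max(capacity_estimate, na.rm = TRUE)

    min_time_for_length <- stats::setNames(
      vapply(config$start_length:config$max_length, function(L) {
        ok <- !is.na(capacity_estimate) & capacity_estimate >= L
        if (any(ok)) times_grid[which(ok)[1L]] else NA_integer_
      }, numeric(1)),
      config$start_length:config$max_length)

    # VRT bisection at the reader's best (length, time).
    vrt_estimate <- NA_real_
    if (!is.na(ceiling_est)) {
      best_len <- ceiling_est
      best_t <- min_time_for_length[[as.character(best_len)]]
      grid <- seq(config$vrt_grid_ms * ceiling(best_t / config$vrt_grid_ms),
                  generous, by = config$vrt_grid_ms)
      lo <- 1L; hi <- length(grid); found <- NA_real_
      # The cell passed at the generous VRT, so a passing point exists w.h.p.
      while (lo <= hi) {
        mid <- (lo + hi) %/% 2L
        res <- administer(best_len, best_t, grid[mid], "vrt_sweep")
        if (res$pass) { found <- grid[mid]; hi <- mid - 1L } else lo <- mid + 1L
      }
      vrt_estimate <- found
    }

    causes <- character()
    if (is.na(ceiling_est) || ceiling_est < config$max_length)
      causes <- c(causes, "trying to recognize too many letters")
    if (!is.na(ceiling_est) &&
        !is.na(capacity_estimate[[as.character(config$start_time_ms)]]) &&
        capacity_estimate[[as.character(config$start_time_ms)]] < ceiling_est)
      causes <- c(causes, "too short a fixation time")
    if (is.na(vrt_estimate) || vrt_estimate > config$max_time_ms)
      causes <- c(causes, "too short a verbal reaction time")

    structure(
      list(capacity_estimate = capacity_estimate,
           min_time_for_length = min_time_for_length,
           vrt_estimate_ms = vrt_estimate,
           trial_log = do.call(rbind, log),
           causes = causes,
           config = config),
      class = "diagnostic_result"
    )
  })
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat("<diagnostic_result>\n")
  cat("  capacity by time (ms):",
      paste0(names(x$capacity_estimate), ":", x$capacity_estimate,
             collapse = " "), "\n")
  cat("  minimal VRT:", x$vrt_estimate_ms, "ms\n")
  cat("  lists administered:",
      sum(x$trial_log$phase != "spell_check") %/% x$config$list_size, "\n")
  if (length(x$causes))
    cat("  causes:", paste(x$causes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.diagnostic_result <- function(object, ...) {
  cat("Recovered reading parameters\n")
  print(data.frame(time_ms = as.numeric(names(object$capacity_estimate)),
                   max_length = as.vector(object$capacity_estimate)))
  cat("Minimal time per length (ms):\n")
  print(object$min_time_for_length)
  cat("Minimal allowed VRT:", object$vrt_estimate_ms, "ms\n")
  invisible(object)
}
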