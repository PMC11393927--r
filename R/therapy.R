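# Unguided vs computer-guided reading simulation.
#
# Unguided reading follows the reader's own strategy and self-chosen
# parameters (250 ms fixations, pronunciation begun at 0.8 x the required
# verbal reaction time, i.e. prematurely). Guided reading enforces the
# diagnosed parameters segment by segment; the reader complies with each
# instruction with probability `compliance`, and the next segment is withheld
# until the previous one is read correctly.

SELF_FIXATION_MS <- 250
SELF_VRT_FACTOR <- 0.8
GUESS_P_HIGH <- 0.5   # >= half the letters recognized
GUESS_P_LOW <- 0.1    # fewer letters recognized
REGRESSION_RATE <- 0.1
HYPERMETRIC_EXCESS <- 2L
SACCADE_MS <- 30

# Letters reliably identified in one attempt: a span within capacity yields
# every visible letter; a span exceeding capacity disrupts simultaneous
# identification and yields only the fixated letter.
recognized_count <- function(reader, len, presentation_ms) {
  cap <- capacity_at(reader, presentation_ms)
  fix <- (len - 1L) %/% 2L
  vis <- length(visible_window(len, fix, reader$field_defect))
  if (len <= cap) vis else min(1L, vis)
}

# Whole-word guessing of a natural word after a failed recognition attempt.
guess_word <- function(reader, len, presentation_ms) {
  n_rec <- recognized_count(reader, len, presentation_ms)
  p <- if (n_rec >= len / 2) GUESS_P_HIGH else GUESS_P_LOW
  stats::runif(1) < p
}

new_session <- function(mode, records, total_time_ms, regressions = 0L) {
  records <- do.call(rbind, records)
  structure(
    list(mode = mode,
         records = records,
         total_segments = nrow(records),
         total_errors = sum(!records$correct),
         total_time_ms = total_time_ms,
         regressions = regressions),
    class = "reading_session"
  )
}

#' @export
print.reading_session <- function(x, ...) {
  cat("<reading_session>", x$mode, "|", x$total_segments, "units |",
      x$total_errors, "errors |", round(x$total_time_ms), "ms\n")
  invisible(x)
}

record_row <- function(unit, len, fixation_ms, allowed_vrt_ms, correct,
                       error_position = NA_integer_, attempts = 1L) {
  data.frame(unit = unit, attempted_length = len, fixation_ms = fixation_ms,
             allowed_vrt_ms = allowed_vrt_ms, correct = correct,
             error_position = error_position, attempts = attempts)
}

# Minimal grid time at which the reader reaches their capacity ceiling.
self_best_time <- function(reader) {
  times <- as.numeric(names(reader$capacity_by_time))
  ceiling_cap <- max(reader$capacity_by_time)
  min(times[reader$capacity_by_time == ceiling_cap])
}

#' Simulate one unguided reading session
#'
#' The reader works through `text` with their own strategy. `whole_word`
#' readers fixate each word at its middle letter for 250 ms and start
#' pronouncing at 0.8 x their required verbal reaction time (prematurely); a
#' failed word may still be guessed (probability 0.5 when at least half its
#' letters were recognized, 0.1 otherwise). `searching` readers behave the
#' same but interleave searching eye movements, roughly doubling reading
#' time. `hypermetric_no_correction` readers jump capacity + 2 letters per
#' saccade, so letters fall into coverage gaps and are never seen.
#' `staircase_segments` readers split the text into capacity-sized segments
#' themselves and allow themselves adequate fixation times and verbal
#' reaction times (correct but slow); `letter_by_letter` readers do the same
#' one letter at a time. Isolated single regressions are interspersed with
#' probability 0.1 per transition; they add time but never change
#' correctness.
#'
#' @param reader a [reader_profile()].
#' @param text the text to read.
#' @param inventory a [cluster_inventory()] (used by segmenting strategies).
#' @param rng_seed optional integer seed.
#' @return a `reading_session`.
#' @export
simulate_unguided <- function(reader, text, inventory = cluster_inventory("de"),
                              rng_seed = NULL) {
  stopifnot(inherits(reader, "reader_profile"))
  words <- tokenize_words(text)
  words <- words[vapply(words, function(w) length(letters_only(w)) > 0, logical(1))]
  if (!length(words)) stop_precondition("text contains no letters")

  with_seed(rng_seed, {
    records <- list()
    total_time <- 0
    self_vrt <- SELF_VRT_FACTOR * reader$required_vrt_ms

    attempt_word <- function(w, fixation_ms, allowed_vrt_ms, guessable = TRUE) {
      len <- length(letters_only(w))
      out <- recognize(reader, w, fixation_ms, allowed_vrt_ms)
      correct <- out$correct
      err_pos <- out$error_position
      if (!correct && guessable && guess_word(reader, len, fixation_ms)) {
        correct <- TRUE
        err_pos <- NA_integer_
      }
      record_row(w, len, fixation_ms, allowed_vrt_ms, correct, err_pos)
    }

    if (reader$strategy %in% c("whole_word", "searching")) {
      for (w in words) {
        records[[length(records) + 1L]] <-
          attempt_word(w, SELF_FIXATION_MS, self_vrt)
        total_time <- total_time + SELF_FIXATION_MS + SACCADE_MS
      }
      if (reader$strategy == "searching") total_time <- 2 * total_time

    } else if (reader$strategy == "staircase_segments") {
      cap <- max(reader$capacity_by_time)
      t_ok <- self_best_time(reader)
      plan <- segment_text(paste(words, collapse = " "), cap, inventory)
      for (i in seq_len(nrow(plan$segments))) {
        seg <- plan$segments$text[i]
        out <- recognize(reader, seg, t_ok, reader$required_vrt_ms)
        records[[length(records) + 1L]] <- record_row(
          seg, nchar(seg), t_ok, reader$required_vrt_ms, out$correct,
          out$error_position)
        total_time <- total_time + t_ok + SACCADE_MS
      }

    } else if (reader$strategy == "letter_by_letter") {
      t_ok <- self_best_time(reader)
      for (w in words) {
        chars <- letters_only(w)
        outs <- lapply(chars, function(ch)
          recognize(reader, ch, t_ok, reader$required_vrt_ms))
        bad <- which(!vapply(outs, `[[`, logical(1), "correct"))
        records[[length(records) + 1L]] <- record_row(
          w, length(chars), t_ok, reader$required_vrt_ms,
          length(bad) == 0L,
          if (length(bad)) bad[[1L]] - 1L else NA_integer_)
        total_time <- total_time + length(chars) * (t_ok + SACCADE_MS)
      }

    } else { # hypermetric_no_correction
      cap <- max(1L, capacity_at(reader, SELF_FIXATION_MS))
      stream <- paste(unlist(lapply(words, letters_only)), collapse = "")
      n <- nchar(stream)
      step <- cap + HYPERMETRIC_EXCESS
      fix_idx <- seq((cap - 1L) %/% 2L, n - 1L, by = step)
      gaps <- find_gaps(data.frame(index = fix_idx, window_length = cap), stream)
      covered <- rep(TRUE, n)
      if (nrow(gaps$skipped)) {
        for (g in seq_len(nrow(gaps$skipped)))
          covered[(gaps$skipped$start[g] + 1L):gaps$skipped$end[g]] <- FALSE
      }
      offset <- 0L
      for (w in words) {
        len <- length(letters_only(w))
        seen <- sum(covered[(offset + 1L):(offset + len)])
        p_guess <- if (seen >= len / 2) GUESS_P_HIGH else GUESS_P_LOW
        correct <- seen == len &&
          recognize(reader, w, SELF_FIXATION_MS, self_vrt)$correct
        err_pos <- NA_integer_
        if (!correct && stats::runif(1) < p_guess) correct <- TRUE
        if (!correct) {
          unseen <- which(!covered[(offset + 1L):(offset + len)]) - 1L
          err_pos <- if (length(unseen)) unseen[[1L]] else
            sample.int(len, 1L) - 1L
        }
        records[[length(records) + 1L]] <- record_row(
          w, len, SELF_FIXATION_MS, self_vrt, correct, err_pos)
        offset <- offset + len
        total_time <- total_time + SELF_FIXATION_MS + SACCADE_MS
      }
    }

    # Isolated single regressions between attempt units: extra fixations that
    # never alter correctness.
    n_trans <- max(0L, length(records) - 1L)
    regressions <- sum(stats::runif(n_trans) < REGRESSION_RATE)
    total_time <- total_time + regressions * (SELF_FIXATION_MS + SACCADE_MS)

    new_session("unguided", records, total_time, regressions)
  })
}

#' Simulate one computer-guided reading session
#'
#' The text is segmented at the diagnosed `capacity`; the guidance cursor
#' enforces `fixation_ms` and `allowed_vrt_ms` on every segment. On each
#' attempt the reader follows the instructions with probability
#' `reader$compliance`; otherwise the self-chosen unguided parameters apply
#' to that attempt. The next segment is only displayed once the previous one
#' is read correctly: failed segments are re-attempted (and counted as one
#' error, however many attempts they need).
#'
#' @param reader a [reader_profile()].
#' @param text the text to read.
#' @param capacity segment capacity (letters), from the reader's diagnosis.
#' @param fixation_ms enforced fixation time (ms), on the 50 ms grid
#'   250..500.
#' @param allowed_vrt_ms enforced verbal reaction time (ms), a multiple of
#'   the 50 ms grid.
#' @param inventory a [cluster_inventory()].
#' @param rng_seed optional integer seed.
#' @param max_attempts re-attempt guard per segment; a segment still unread
#'   after this many attempts is abandoned (counted as its one error).
#' @return a `reading_session`.
#' @export
simulate_guided <- function(reader, text, capacity, fixation_ms,
                            allowed_vrt_ms, inventory = cluster_inventory("de"),
                            rng_seed = NULL, max_attempts = 25L) {
  stopifnot(inherits(reader, "reader_profile"))
  if (!fixation_ms %in% seq(250, 500, by = 50))
    stop_precondition("fixation_ms must lie on the 50 ms grid 250..500")
  if (allowed_vrt_ms <= 0 || allowed_vrt_ms %% 50 != 0)
    stop_precondition("allowed_vrt_ms must be a positive multiple of 50 ms")

  plan <- segment_text(text, capacity, inventory)
  with_seed(rng_seed, {
    records <- list()
    total_time <- 0
    self_vrt <- SELF_VRT_FACTOR * reader$required_vrt_ms
    for (i in seq_len(nrow(plan$segments))) {
      seg <- plan$segments$text[i]
      attempts <- 0L
      first_correct <- NA
      first_err <- NA_integer_
      repeat {
        attempts <- attempts + 1L
        compliant <- stats::runif(1) < reader$compliance
        out <- if (compliant) {
          recognize(reader, seg, fixation_ms, allowed_vrt_ms)
        } else {
          recognize(reader, seg, SELF_FIXATION_MS, self_vrt)
        }
        total_time <- total_time +
          (if (compliant) fixation_ms else SELF_FIXATION_MS) + SACCADE_MS
        if (attempts == 1L) {
          first_correct <- out$correct
          first_err <- out$error_position
        }
        if (out$correct || attempts >= max_attempts) break
      }
      records[[length(records) + 1L]] <- record_row(
        seg, nchar(seg), fixation_ms, allowed_vrt_ms, first_correct,
        first_err, attempts)
    }
    new_session("guided", records, total_time)
  })
}

#' Percentage decrease in reading errors
#'
#' @param errors_before error count before (must be positive).
#' @param errors_after error count after.
#' @return `100 * (errors_before - errors_after) / errors_before`.
#' @examples
#' error_reduction(30, 9)  # 70
#' @export
error_reduction <- function(errors_before, errors_after) {
  if (!is.numeric(errors_before) || errors_before <= 0)
    stop_precondition("errors_before must be positive (reduction undefined at 0)")
  100 * (errors_before - errors_after) / errors_before
}

#' Hedges g effect size
#'
#' Standardized mean difference `(mean(group_a) - mean(group_b)) / s_pooled`
#' with the small-sample correction `1 - 3 / (4 (n_a + n_b) - 9)`, where
#' `s_pooled` is the square root of the df-weighted average of the two sample
#' variances. With error counts, pass the control group as `group_a` and the
#' treatment group as `group_b` so that fewer treatment errors give positive
#' g.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return the effect size (unitless).
#' @examples
#' hedges_g(c(10, 12, 14), c(2, 4, 6))  # 3.2
#' @export
hedges_g <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop_precondition("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop_precondition("pooled variance is zero; g undefined")
  correction <- 1 - 3 / (4 * (na + nb) - 9)
  (mean(group_a) - mean(group_b)) / sqrt(sp2) * correction
}

#' Error-position profile over reading sessions
#'
#' Tallies letter-level error positions across sessions for items of one
#' length and tests the counts against a uniform distribution (chi-square
#' goodness of fit). Reading errors occurring equally often at all positions
#' — no excess at word beginnings, ends, or crowded interior letters — is
#' the expected profile when errors stem from capacity and timing limits
#' rather than positional visual effects.
#'
#' @param sessions a list of `reading_session` objects (or a single one).
#' @param item_length restrict to attempts of this length; default: the most
#'   frequent length among error trials.
#' @return list with `counts` (per 0-based position), `chisq` the test
#'   statistic, `p_value`, and `item_length`.
#' @export
error_position_profile <- function(sessions, item_length = NULL) {
  if (inherits(sessions, "reading_session")) sessions <- list(sessions)
  recs <- do.call(rbind, lapply(sessions, `[[`, "records"))
  errs <- recs[!recs$correct & !is.na(recs$error_position), , drop = FALSE]
  if (!nrow(errs)) stop_precondition("no letter-level errors recorded")
  if (is.null(item_length)) {
    tab <- table(errs$attempted_length)
    item_length <- as.integer(names(tab)[which.max(tab)])
  }
  errs <- errs[errs$attempted_length == item_length, , drop = FALSE]
  counts <- tabulate(errs$error_position + 1L, nbins = item_length)
  names(counts) <- 0:(item_length - 1L)
  # small samples only degrade the chi-square approximation, not the tally
  test <- suppressWarnings(stats::chisq.test(counts))
  list(counts = counts, chisq = unname(test$statistic),
       p_value = unname(test$p.value), item_length = item_length)
}

#' Synthetic reading text
#'
#' Samples words from a reference lexicon to build a reading text of roughly
#' `n_letters` letters — the material for one therapy session.
#'
#' @param n_letters approximate total letter count (default 600, about 200
#'   three-letter segments).
#' @param lexicon word stock to draw from; default the bundled German
#'   lexicon.
#' @param rng_seed optional integer seed.
#' @return a single string of space-separated words.
#' @export
synthetic_text <- function(n_letters = 600L, lexicon = default_lexicon(),
                           rng_seed = NULL) {
  with_seed(rng_seed, {
    out <- character()
    total <- 0L
    while (total < n_letters) {
      w <- sample(lexicon, 1L)
      out <- c(out, w)
      total <- total + nchar(w)
    }
    paste(out, collapse = " ")
  })
}

#' Run the cohort therapy experiment
#'
#' Samples a synthetic cohort, diagnoses every reader with the pseudoword
#' staircase, then has each reader read the same text twice: unguided (own
#' strategy, self-chosen parameters) and computer-guided at the reader's own
#' diagnosed capacity, fixation time and verbal reaction time. Pooled error
#' counts give the percentage error reduction; per-reader counts give the
#' Hedges g between the unguided (control) and guided (treatment) conditions.
#'
#' @param n_readers cohort size (default 50).
#' @param text reading material; default [synthetic_text()] (about 600
#'   letters, around 200 three-letter segments).
#' @param preset cohort VRT preset, see [sample_cohort()].
#' @param rng_seed integer seed governing the whole experiment.
#' @return a `therapy_outcome`: `errors_unguided`, `errors_guided`,
#'   `reduction_percent`, `hedges_g`, and `per_reader` (data.frame with one
#'   row per reader: diagnosed parameters and both error counts).
#' @examples
#' \donttest{
#' out <- run_therapy_experiment(n_readers = 10, rng_seed = 1)
#' out$reduction_percent
#' }
#' @export
run_therapy_experiment <- function(n_readers = 50L, text = NULL,
                                   preset = "low_vrt", rng_seed = NULL) {
  with_seed(rng_seed, {
    cohort <- sample_cohort(n_readers, preset)
    if (is.null(text)) text <- synthetic_text()
    inv <- cluster_inventory("de")
    src <- pseudoword_source()
    per <- lapply(seq_along(cohort), function(i) {
      reader <- cohort[[i]]
      diag <- run_staircase(reader, items_fn = src)
      cap <- max(diag$capacity_estimate, na.rm = TRUE)
      fix <- diag$min_time_for_length[[as.character(cap)]]
      vrt <- diag$vrt_estimate_ms
      if (is.na(vrt)) vrt <- diag$config$max_time_ms + 3000
      ung <- simulate_unguided(reader, text, inv)
      gui <- simulate_guided(reader, text, cap, fix, vrt, inv)
      data.frame(reader = i,
                 capacity = cap, fixation_ms = fix, vrt_ms = vrt,
                 errors_unguided = ung$total_errors,
                 errors_guided = gui$total_errors,
                 segments_guided = gui$total_segments,
                 words = ung$total_segments)
    })
    per <- do.call(rbind, per)
    eu <- sum(per$errors_unguided)
    eg <- sum(per$errors_guided)
    structure(
      list(errors_unguided = eu,
           errors_guided = eg,
           reduction_percent = error_reduction(eu, eg),
           hedges_g = hedges_g(per$errors_unguided, per$errors_guided),
           per_reader = per),
      class = "therapy_outcome"
    )
  })
}

#' @export
print.therapy_outcome <- function(x, ...) {
  cat("<therapy_outcome>\n")
  cat("  errors unguided:", x$errors_unguided,
      "| guided:", x$errors_guided, "\n")
  cat("  error reduction:", sprintf("%.1f%%", x$reduction_percent), "\n")
  cat("  Hedges g (unguided vs guided):", sprintf("%.2f", x$hedges_g), "\n")
  invisible(x)
}
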