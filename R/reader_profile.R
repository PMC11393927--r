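#' Visual field defect description
#'
#' Describes a homonymous visual field defect of a reader and, optionally, the
#' compensatory gaze strategy adopted for it. A right-sided defect that
#' involves the fovea hides letters to the right of the fixated letter; the
#' compensation for it is to direct the gaze to the end of the word segment
#' (`gaze_to_end`), which projects the whole segment into the spared left
#' hemifield. Symmetrically, a left-sided foveal defect is compensated by
#' fixating the beginning of the segment (`gaze_to_beginning`). Any other
#' side/compensation pairing is rejected as meaningless.
#'
#' @param side `"left"` or `"right"`: the blind hemifield.
#' @param foveal_involvement logical; does the defect include the fovea? Only
#'   foveal defects mask letters of a word presented at fixation.
#' @param compensation `"none"`, `"gaze_to_end"` (right-sided defects only) or
#'   `"gaze_to_beginning"` (left-sided defects only).
#' @return An object of class `visual_field_defect`.
#' @examples
#' visual_field_defect("right", TRUE, "gaze_to_end")
#' @export
visual_field_defect <- function(side = c("left", "right"),
                                foveal_involvement = TRUE,
                                compensation = c("none", "gaze_to_end",
                                                 "gaze_to_beginning")) {
  side <- match.arg(side)
  compensation <- match.arg(compensation)
  stopifnot(is.logical(foveal_involvement), length(foveal_involvement) == 1L)
  if (compensation == "gaze_to_end" && side != "right")
    stop_precondition("compensation 'gaze_to_end' is only meaningful for side = 'right'")
  if (compensation == "gaze_to_beginning" && side != "left")
    stop_precondition("compensation 'gaze_to_beginning' is only meaningful for side = 'left'")
  structure(
    list(side = side, foveal_involvement = foveal_involvement,
         compensation = compensation),
    class = "visual_field_defect"
  )
}

#' Parametric virtual reader
#'
#' A reader is described by the quantities the tachistoscopic pseudoword
#' experiments vary per child: how many letters can be recognized
#' simultaneously at each fixation time, the minimal verbal reaction time
#' (VRT) needed before correct pronunciation can begin, a residual lapse
#' rate, the eye-movement strategy used for free text, an optional visual
#' field defect, compliance with on-screen guidance, and letter pairs whose
#' sounds are exchanged at pronunciation.
#'
#' @param capacity_by_time named integer vector mapping presentation time in
#'   ms (names) to the maximum number of letters recognizable simultaneously.
#'   Must be defined at least on the 50 ms grid 250..500 and be monotone
#'   non-decreasing in time; the 500 ms value (the ceiling) must lie in 0..8.
#' @param required_vrt_ms minimal time (ms, > 0) from fixation onset to the
#'   earliest correct pronunciation.
#' @param lapse_rate probability in \[0, 0.05\] of an error even when all
#'   conditions for recognition are met.
#' @param strategy unguided-reading strategy: `"whole_word"`,
#'   `"staircase_segments"`, `"searching"`, `"hypermetric_no_correction"` or
#'   `"letter_by_letter"`.
#' @param field_defect optional [visual_field_defect()].
#' @param compliance probability in \[0, 1\] of obeying a guidance instruction
#'   on any one segment.
#' @param grapheme_confusions character vector of two-letter strings, each an
#'   unordered confusable pair (e.g. `"pq"`, `"bd"`, `"mn"`); may be empty.
#' @return An object of class `reader_profile`.
#' @examples
#' r <- reader_profile(
#'   capacity_by_time = c(`250` = 3, `300` = 4, `350` = 4,
#'                        `400` = 5, `450` = 5, `500` = 6),
#'   required_vrt_ms = 1400
#' )
#' print(r)
#' @export
reader_profile <- function(capacity_by_time,
                           required_vrt_ms,
                           lapse_rate = 0,
                           strategy = c("whole_word", "staircase_segments",
                                        "searching", "hypermetric_no_correction",
                                        "letter_by_letter"),
                           field_defect = NULL,
                           compliance = 1,
                           grapheme_confusions = character()) {
  strategy <- match.arg(strategy)
  if (is.null(names(capacity_by_time)) || any(!nzchar(names(capacity_by_time))))
    stop_precondition("capacity_by_time must be a named vector (names = times in ms)")
  times <- as.numeric(names(capacity_by_time))
  if (anyNA(times)) stop_precondition("capacity_by_time names must be numeric times in ms")
  o <- order(times)
  times <- times[o]
  caps <- as.integer(capacity_by_time[o])
  if (!all(c(250, 300, 350, 400, 450, 500) %in% times))
    stop_precondition("capacity_by_time must be defined at least on {250, 300, ..., 500} ms")
  if (any(caps < 0)) stop_precondition("capacities must be non-negative")
  if (is.unsorted(caps)) stop_precondition("capacity_by_time must be monotone non-decreasing in time")
  ceiling_cap <- caps[match(500, times)]
  if (ceiling_cap > 8L)
    stop_precondition("capacity at 500 ms (the ceiling) must be in 0..8")
  if (!(is.numeric(required_vrt_ms) && length(required_vrt_ms) == 1L && required_vrt_ms > 0))
    stop_precondition("required_vrt_ms must be a single positive number")
  if (!(is.numeric(lapse_rate) && length(lapse_rate) == 1L &&
        lapse_rate >= 0 && lapse_rate <= 0.05))
    stop_precondition("lapse_rate must lie in [0, 0.05]")
  if (!(is.numeric(compliance) && length(compliance) == 1L &&
        compliance >= 0 && compliance <= 1))
    stop_precondition("compliance must lie in [0, 1]")
  if (!is.null(field_defect) && !inherits(field_defect, "visual_field_defect"))
    stop_precondition("field_defect must be NULL or a visual_field_defect object")
  grapheme_confusions <- as.character(grapheme_confusions)
  if (length(grapheme_confusions) &&
      any(nchar(grapheme_confusions) != 2L))
    stop_precondition("grapheme_confusions entries must be two-letter strings")

  structure(
    list(
      capacity_by_time = stats::setNames(caps, as.character(times)),
      required_vrt_ms = as.numeric(required_vrt_ms),
      lapse_rate = lapse_rate,
      strategy = strategy,
      field_defect = field_defect,
      compliance = compliance,
      grapheme_confusions = tolower(grapheme_confusions)
    ),
    class = "reader_profile"
  )
}

#' @export
print.reader_profile <- function(x, ...) {
  cat("<reader_profile>\n")
  cat("  capacity by fixation time (ms):",
      paste0(names(x$capacity_by_time), ":", x$capacity_by_time, collapse = " "), "\n")
  cat("  required VRT:", x$required_vrt_ms, "ms | lapse:", x$lapse_rate,
      "| compliance:", x$compliance, "\n")
  cat("  strategy:", x$strategy, "\n")
  if (!is.null(x$field_defect))
    cat("  field defect:", x$field_defect$side,
        if (x$field_defect$foveal_involvement) "(foveal)" else "(sparing fovea)",
        "compensation:", x$field_defect$compensation, "\n")
  if (length(x$grapheme_confusions))
    cat("  grapheme confusions:", paste(x$grapheme_confusions, collapse = ", "), "\n")
  invisible(x)
}

#' Letter capacity at a presentation time
#'
#' Looks up the number of letters the reader can recognize simultaneously at
#' `presentation_ms`. Times off the defined grid clamp down to the nearest
#' defined level at or below; times below the lowest defined level yield 0
#' (no defined capacity).
#'
#' @param reader a [reader_profile()].
#' @param presentation_ms presentation (fixation) time in ms.
#' @return integer capacity.
#' @export
capacity_at <- function(reader, presentation_ms) {
  stopifnot(inherits(reader, "reader_profile"))
  times <- as.numeric(names(reader$capacity_by_time))
  ok <- times <= presentation_ms
  if (!any(ok)) return(0L)
  reader$capacity_by_time[[which(ok)[sum(ok)]]]
}

#' Letters visible within one fixation
#'
#' Returns the 0-based letter positions of a word of `word_length` letters
#' that fall into the seeing field when the reader fixates position
#' `fixation_index`. With no defect, or with a defect sparing the fovea (the
#' word is assumed to lie within the spared central field), all positions are
#' visible. A right-sided foveal defect hides everything right of fixation; a
#' left-sided foveal defect hides everything left of it. A compensatory gaze
#' strategy overrides the requested fixation index: `gaze_to_end` fixates the
#' last letter, `gaze_to_beginning` the first.
#'
#' @param word_length positive integer number of letters.
#' @param fixation_index 0-based fixated letter position.
#' @param defect optional [visual_field_defect()].
#' @return sorted integer vector of visible 0-based positions.
#' @examples
#' visible_window(6, 2, visual_field_defect("right", TRUE, "none"))
#' visible_window(6, 2, visual_field_defect("right", TRUE, "gaze_to_end"))
#' @export
visible_window <- function(word_length, fixation_index, defect = NULL) {
  if (!is_count(word_length))
    stop_precondition("word_length must be a positive integer")
  if (!is_count(fixation_index, min = 0L) || fixation_index >= word_length)
    stop_precondition("fixation_index must satisfy 0 <= fixation_index < word_length")
  all_idx <- seq_len(word_length) - 1L
  if (is.null(defect) || !defect$foveal_involvement) return(all_idx)
  fix <- switch(defect$compensation,
    none = as.integer(fixation_index),
    gaze_to_end = word_length - 1L,
    gaze_to_beginning = 0L
  )
  if (defect$side == "right") 0L:fix else fix:(word_length - 1L)
}

#' Simulate one tachistoscopic recognition attempt
#'
#' A word is recognized correctly iff (i) every letter falls into the seeing
#' field, (ii) the word is no longer than the reader's letter capacity at the
#' presentation time, (iii) the allowed verbal reaction time is at least the
#' reader's required VRT, (iv) no lapse occurs, and (v) no grapheme-confusion
#' event occurs (each letter belonging to a confusable pair is exchanged
#' independently with probability 0.5). The word is fixated at its middle
#' letter (left of center for even lengths) unless a compensatory gaze
#' strategy overrides this.
#'
#' @param reader a [reader_profile()].
#' @param word a letter string (non-letters are ignored).
#' @param presentation_ms presentation (fixation) time in ms.
#' @param allowed_vrt_ms time in ms granted before pronunciation must begin.
#' @param rng_seed optional integer; when given the outcome is a deterministic
#'   function of the arguments.
#' @return A `trial_outcome` list: `correct`, `visible_indices` (0-based),
#'   `error_position` (0-based, `NA` unless the error is letter-level) and
#'   `vrt_used_ms`.
#' @examples
#' r <- reader_profile(c(`250` = 3, `300` = 4, `350` = 4, `400` = 5,
#'                       `450` = 5, `500` = 6), required_vrt_ms = 1400)
#' recognize(r, "blirk", 400, 1500, rng_seed = 1)
#' @export
recognize <- function(reader, word, presentation_ms, allowed_vrt_ms,
                      rng_seed = NULL) {
  stopifnot(inherits(reader, "reader_profile"))
  chars <- letters_only(word)
  len <- length(chars)
  if (len == 0L) stop_precondition("word must contain at least one letter")
  if (!(is.numeric(presentation_ms) && presentation_ms > 0))
    stop_precondition("presentation_ms must be positive")
  if (!(is.numeric(allowed_vrt_ms) && allowed_vrt_ms > 0))
    stop_precondition("allowed_vrt_ms must be positive")

  with_seed(rng_seed, {
    fix <- (len - 1L) %/% 2L
    visible <- visible_window(len, fix, reader$field_defect)
    cap <- capacity_at(reader, presentation_ms)

    window_ok <- length(visible) == len
    cap_ok <- len <= cap
    vrt_ok <- allowed_vrt_ms >= reader$required_vrt_ms
    lapse <- stats::runif(1) < reader$lapse_rate

    confused_at <- integer()
    if (length(reader$grapheme_confusions)) {
      confusable <- unique(unlist(strsplit(reader$grapheme_confusions, "")))
      eligible <- which(chars %in% confusable) - 1L
      if (length(eligible)) {
        hits <- stats::runif(length(eligible)) < 0.5
        confused_at <- eligible[hits]
      }
    }

    correct <- window_ok && cap_ok && vrt_ok && !lapse && !length(confused_at)
    error_position <- NA_integer_
    if (!correct) {
      if (!window_ok) {
        unseen <- setdiff(seq_len(len) - 1L, visible)
        error_position <- if (length(unseen) == 1L) unseen else
          sample(unseen, 1L)
      } else if (!cap_ok || lapse) {
        error_position <- if (len == 1L) 0L else sample.int(len, 1L) - 1L
      } else if (length(confused_at)) {
        error_position <- confused_at[[1L]]
      } # VRT-only failure: not a letter-level error
    }

    structure(
      list(correct = correct,
           visible_indices = visible,
           error_position = error_position,
           vrt_used_ms = if (vrt_ok) reader$required_vrt_ms else allowed_vrt_ms),
      class = "trial_outcome"
    )
  })
}
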