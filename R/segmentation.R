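#' Segment a text into readable word segments
#'
#' Splits each whitespace-delimited word, greedily left to right, into
#' segments of at most `capacity` letters, never breaking inside a grapheme
#' cluster (longest match first): when the greedy boundary falls inside a
#' cluster the segment is shortened to the nearest allowed boundary. Word
#' boundaries are always allowed. Coordinates are 0-based, half-open indices
#' into the letters-only stream (whitespace and punctuation are excluded from
#' letter counts but each segment remembers its source word).
#'
#' @param text UTF-8 text.
#' @param capacity maximum letters per segment (the reader's simultaneous
#'   letter span); must be at least 2 and at least the longest cluster
#'   occurring in the text.
#' @param inventory a [cluster_inventory()]; defaults to the German one.
#' @param natural_bonus allow natural-word segments one letter beyond the
#'   pseudoword capacity (off by default: only some readers tolerate longer
#'   natural words).
#' @return a `segment_plan` with `segments` (data.frame: start, end, text,
#'   word), `capacity`, `stream` (the letter stream as one string); fixation
#'   targets and saccade amplitudes are filled by [plan_saccades()].
#' @examples
#' plan <- segment_text("flasche und bier", 4, cluster_inventory("de"))
#' plan$segments
#' @export
segment_text <- function(text, capacity, inventory = cluster_inventory("de"),
                         natural_bonus = FALSE) {
  if (!is_count(capacity, 2L))
    stop_precondition("capacity must be an integer >= 2")
  if (isTRUE(natural_bonus)) capacity <- capacity + 1L
  words <- tokenize_words(text)
  words <- words[vapply(words, function(w) length(letters_only(w)) > 0, logical(1))]
  if (!length(words)) stop_precondition("text contains no letters")

  segs <- list()
  offset <- 0L
  for (w in words) {
    chars <- letters_only(w)
    n <- length(chars)
    spans <- cluster_spans(chars, inventory)
    if (nrow(spans) && any(spans[, "end"] - spans[, "start"] > capacity)) {
      bad <- which(spans[, "end"] - spans[, "start"] > capacity)[1L]
      stop_precondition("unsegmentable input: cluster '",
                        paste(chars[(spans[bad, 1] + 1):spans[bad, 2]], collapse = ""),
                        "' in '", w, "' is longer than capacity ", capacity)
    }
    allowed <- c(split_points(w, inventory), n)  # word end always allowed
    pos <- 0L
    while (pos < n) {
      b <- min(pos + capacity, n)
      while (!(b %in% allowed) && b > pos) b <- b - 1L
      if (b <= pos)
        stop_precondition("unsegmentable input at '", w,
                          "': no allowed boundary within capacity ", capacity)
      segs[[length(segs) + 1L]] <- data.frame(
        start = offset + pos, end = offset + b,
        text = paste(chars[(pos + 1L):b], collapse = ""), word = w)
      pos <- b
    }
    offset <- offset + n
  }
  structure(
    list(segments = do.call(rbind, segs),
         capacity = as.integer(capacity),
         stream = paste(unlist(lapply(words, letters_only)), collapse = ""),
         fixation_targets = NULL,
         amplitudes = NULL),
    class = "segment_plan"
  )
}

#' Plan fixation targets and saccade amplitudes for a segment plan
#'
#' The fixation target of each segment is its middle letter (left of center
#' for even lengths), as the guidance cursor prescribes; the amplitude of
#' each saccade is the letter distance between consecutive fixation targets.
#' For contiguous segments of length at most k every amplitude is at most
#' k + 1.
#'
#' @param plan a [segment_text()] result.
#' @return the plan with `fixation_targets` (0-based global letter indices)
#'   and `amplitudes` filled.
#' @export
plan_saccades <- function(plan) {
  stopifnot(inherits(plan, "segment_plan"))
  s <- plan$segments
  if (is.null(s) || !nrow(s)) stop_precondition("plan has no segments")
  len <- s$end - s$start
  plan$fixation_targets <- s$start + (len - 1L) %/% 2L
  plan$amplitudes <- diff(plan$fixation_targets)
  plan
}

#' @export
print.segment_plan <- function(x, ...) {
  cat("<segment_plan> capacity", x$capacity, "|", nrow(x$segments),
      "segments over", nchar(x$stream), "letters\n")
  cat(" ", paste(x$segments$text, collapse = " | "), "\n")
  if (!is.null(x$amplitudes) && length(x$amplitudes))
    cat("  amplitudes:", paste(x$amplitudes, collapse = " "), "\n")
  invisible(x)
}

#' Report coverage gaps between fixated windows
#'
#' Given the fixations actually executed (fixated letter index and window
#' length, the window being centred on the fixated letter, left of centre
#' for even window lengths), reports every maximal run of letters covered by
#' no window — the letters that are never seen when saccade amplitudes exceed
#' the recognizable window, as with hypermetric saccades that skip material
#' between word segments.
#'
#' @param fixations data.frame (or list coercible to one) with columns
#'   `index` (0-based fixated letter, strictly increasing) and
#'   `window_length`.
#' @param stream the letter stream that was read: a string, or just its
#'   length.
#' @return a `gap_report`: data.frame `skipped` with `start`, `end`
#'   (half-open) and `text` (`NA` when only a length was supplied).
#' @examples
#' find_gaps(data.frame(index = c(1, 9), window_length = 4),
#'           "abcdtoefghbe")
#' @export
find_gaps <- function(fixations, stream) {
  fx <- as.data.frame(fixations)
  if (!all(c("index", "window_length") %in% names(fx)))
    stop_precondition("fixations needs columns 'index' and 'window_length'")
  if (is.unsorted(fx$index, strictly = TRUE))
    stop_precondition("fixation indices must be strictly increasing")
  stream_chr <- if (is.character(stream)) paste(letters_only(stream), collapse = "") else NULL
  n <- if (is.null(stream_chr)) as.integer(stream) else nchar(stream_chr)

  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(fx))) {
    w <- fx$window_length[i]
    start <- fx$index[i] - (w - 1L) %/% 2L
    idx <- seq(start, start + w - 1L)
    idx <- idx[idx >= 0L & idx < n]
    covered[idx + 1L] <- TRUE
  }
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gaps <- which(!runs$values)
  skipped <- if (length(gaps)) {
    data.frame(
      start = starts[gaps] - 1L,
      end = ends[gaps],
      text = if (is.null(stream_chr)) rep(NA_character_, length(gaps)) else
        substring(stream_chr, starts[gaps], ends[gaps])
    )
  } else {
    data.frame(start = integer(), end = integer(), text = character())
  }
  structure(list(skipped = skipped, stream_length = n), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (!nrow(x$skipped)) {
    cat("<gap_report> no gaps:", x$stream_length, "letters fully covered\n")
  } else {
    cat("<gap_report>", nrow(x$skipped), "gap(s):\n")
    print(x$skipped)
  }
  invisible(x)
}
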