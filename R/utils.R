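# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so callers' RNG streams are unaffected.
#' A `NULL` seed evaluates the expression against the ambient stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Extract the letter stream of a string: alphabetic characters only,
# case-folded.  Coordinates everywhere in the package are 0-based indices
# into this stream.
letters_only <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  tolower(chars[grepl("[[:alpha:]]", chars)])
}

# Split a text into whitespace-delimited word tokens, dropping empties.
tokenize_words <- function(text) {
  w <- strsplit(text, "[[:space:]]+")[[1]]
  w[nzchar(w)]
}

stop_precondition <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}
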