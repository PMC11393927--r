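#' Grapheme cluster inventories
#'
#' Some letter sequences correspond to a single phoneme ("sch", "ch", "ie",
#' "ah" in German; "ea", "au", "oa" in English; "eau", "eaux", "au", "en" in
#' French) and must never be split across reading segments. An inventory
#' holds such clusters for one language; matching is longest-cluster-first,
#' left to right.
#'
#' @param language language identifier (e.g. `"de"`).
#' @param clusters character vector of clusters, each at least 2 letters.
#' @return A `cluster_inventory` object.
#' @examples
#' cluster_inventory("de")            # built-in German defaults
#' cluster_inventory("xx", c("th"))   # custom
#' @export
cluster_inventory <- function(language, clusters = NULL) {
  if (is.null(clusters)) {
    clusters <- builtin_clusters()[[language]]
    if (is.null(clusters))
      stop_precondition("no built-in cluster inventory for language '", language,
                        "'; supply `clusters` explicitly")
  }
  clusters <- tolower(as.character(clusters))
  if (length(clusters) && any(nchar(clusters) < 2L))
    stop_precondition("each cluster must have length >= 2")
  structure(
    list(language = language,
         clusters = clusters[order(-nchar(clusters), clusters)]),
    class = "cluster_inventory"
  )
}

# Built-in inventories. Entries beyond the quoted examples (German ei/eu,
# English aw, French ou) are editable defaults, not fixed constants; pass a
# custom `clusters` vector to override.
builtin_clusters <- function() {
  path <- system.file("extdata", "clusters.json", package = "lexidiag")
  if (nzchar(path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    list(de = c("sch", "ch", "ie", "ah", "ei", "eu"),
         en = c("ea", "au", "oa", "aw"),
         fr = c("eaux", "eau", "au", "en", "ou"))
  }
}

#' @export
print.cluster_inventory <- function(x, ...) {
  cat("<cluster_inventory> language:", x$language, "\n  clusters:",
      paste(x$clusters, collapse = ", "), "\n")
  invisible(x)
}

# Longest-match, left-to-right, non-overlapping cluster occurrences in a
# letter vector. Returns a matrix with columns start/end (0-based, half-open).
cluster_spans <- function(chars, inventory) {
  if (is.null(inventory) || !length(inventory$clusters))
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  n <- length(chars)
  word <- paste(chars, collapse = "")
  spans <- NULL
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (cl in inventory$clusters) {  # sorted longest first
      k <- nchar(cl)
      if (i + k - 1L <= n && substr(word, i, i + k - 1L) == cl) {
        spans <- rbind(spans, c(i - 1L, i - 1L + k))
        matched <- k
        break
      }
    }
    i <- i + max(1L, matched)
  }
  if (is.null(spans))
    spans <- matrix(integer(), ncol = 2)
  dimnames(spans) <- list(NULL, c("start", "end"))
  spans
}

#' Allowed split positions of a word
#'
#' Returns the internal boundary positions of `word` at which a segment break
#' is allowed: boundary `i` separates letters `i - 1` and `i` (0-based), and a
#' boundary is forbidden iff it falls strictly inside a grapheme-cluster
#' occurrence (longest match first, leftmost on overlap).
#'
#' @param word a letter string (non-letters ignored).
#' @param inventory a [cluster_inventory()].
#' @return sorted integer vector of allowed internal boundaries.
#' @examples
#' split_points("flasche", cluster_inventory("de"))  # 1 2 3 6: not inside "sch"
#' @export
split_points <- function(word, inventory) {
  chars <- letters_only(word)
  n <- length(chars)
  if (n == 0L) stop_precondition("word must contain at least one letter")
  if (n == 1L) return(integer())
  internal <- 1:(n - 1L)
  spans <- cluster_spans(chars, inventory)
  forbidden <- integer()
  if (nrow(spans)) {
    for (r in seq_len(nrow(spans))) {
      s <- spans[r, "start"]; e <- spans[r, "end"]
      if (e - s >= 2L) forbidden <- c(forbidden, (s + 1L):(e - 1L))
    }
  }
  setdiff(internal, forbidden)
}

#' Read a reference lexicon
#'
#' One word per line, UTF-8, case-insensitive; empty lines and non-letter
#' characters are dropped.
#'
#' @param path file path.
#' @return character vector of lower-case words.
#' @export
read_lexicon <- function(path) {
  w <- readLines(path, encoding = "UTF-8", warn = FALSE)
  w <- tolower(trimws(w))
  w <- vapply(w, function(x) paste(letters_only(x), collapse = ""), character(1),
              USE.NAMES = FALSE)
  unique(w[nzchar(w)])
}

#' The bundled German reference lexicon (common colloquial words)
#' @return character vector of words.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_de.txt", package = "lexidiag"))
}

lexicon_bigrams <- function(lexicon) {
  bgs <- unlist(lapply(lexicon, function(w) {
    n <- nchar(w)
    if (n < 2L) return(character())
    substring(w, 1:(n - 1L), 2:n)
  }))
  unique(bgs)
}

#' Generate pronounceable pseudowords
#'
#' Builds `list_size` distinct items of exactly `item_length` letters by
#' bigram-chain sampling: every adjacent letter pair of every item occurs in
#' the reference lexicon's bigram set (the operational pronounceability
#' criterion), and no item equals a lexicon word (case-folded). Candidates
#' violating either property are rejected; after `max_rejections` failed
#' draws a generation-exhausted error is raised.
#'
#' @param item_length letters per item (>= 2).
#' @param list_size number of items (default 20, one diagnostic list).
#' @param lexicon character vector of reference words; defaults to the
#'   bundled German lexicon.
#' @param rng_seed optional integer seed; the same seed reproduces the list.
#' @param max_rejections rejection budget before giving up.
#' @return A `pseudoword_list` with fields `items`, `item_length`,
#'   `list_size`.
#' @examples
#' pw <- generate_pseudowords(4, 5, rng_seed = 7)
#' pw$items
#' @export
generate_pseudowords <- function(item_length, list_size = 20L,
                                 lexicon = default_lexicon(),
                                 rng_seed = NULL, max_rejections = 1e5) {
  if (!is_count(item_length, 2L)) stop_precondition("item_length must be an integer >= 2")
  if (!is_count(list_size)) stop_precondition("list_size must be a positive integer")
  if (!length(lexicon)) stop_precondition("lexicon must be non-empty")
  lexicon <- tolower(lexicon)
  bigrams <- lexicon_bigrams(lexicon)
  if (!length(bigrams))
    stop_precondition("generation exhausted: lexicon contains no bigrams")
  firsts <- substr(bigrams, 1, 1)
  nexts <- split(substr(bigrams, 2, 2), firsts)

  with_seed(rng_seed, {
    items <- character()
    rejections <- 0
    while (length(items) < list_size) {
      cand <- sample(unique(firsts), 1L)
      ok <- TRUE
      for (k in 2:item_length) {
        nx <- nexts[[substr(cand, k - 1L, k - 1L)]]
        if (is.null(nx)) { ok <- FALSE; break }
        cand <- paste0(cand, sample(nx, 1L))
      }
      if (ok && !(cand %in% lexicon) && !(cand %in% items)) {
        items <- c(items, cand)
      } else {
        rejections <- rejections + 1
        if (rejections >= max_rejections)
          stop("generation exhausted: no new pseudoword of length ",
               item_length, " after ", max_rejections, " rejections",
               call. = FALSE)
      }
    }
    structure(
      list(items = items, item_length = as.integer(item_length),
           list_size = as.integer(list_size)),
      class = "pseudoword_list"
    )
  })
}

#' @export
print.pseudoword_list <- function(x, ...) {
  cat("<pseudoword_list>", x$list_size, "items of", x$item_length, "letters\n")
  cat(" ", paste(x$items, collapse = " "), "\n")
  invisible(x)
}

#' A cached pseudoword source for staircase sessions
#'
#' The staircase consumes many lists of the same few lengths. This source
#' generates a pool per length once (via [generate_pseudowords()]) and then
#' samples each requested list from the pool, so items are distinct within a
#' list and cheap to produce.
#'
#' @param lexicon reference lexicon (character vector).
#' @param pool_size items cached per length.
#' @param rng_seed seed for pool construction.
#' @return a function `(item_length, n)` returning `n` distinct items.
#' @export
pseudoword_source <- function(lexicon = default_lexicon(), pool_size = 100L,
                              rng_seed = NULL) {
  pools <- new.env(parent = emptyenv())
  seed_base <- if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  function(item_length, n) {
    key <- as.character(item_length)
    if (is.null(pools[[key]])) {
      seed <- if (is.null(seed_base)) NULL else seed_base + item_length
      pools[[key]] <- generate_pseudowords(
        item_length, pool_size, lexicon = lexicon, rng_seed = seed)$items
    }
    pool <- pools[[key]]
    if (n > length(pool)) stop_precondition("pool too small for list of ", n)
    sample(pool, n)
  }
}
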