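# Shared fixtures: readers, oracles and sessions built in code.

grid_times <- seq(250, 500, by = 50)

make_reader <- function(caps = c(3, 4, 4, 5, 5, 6), vrt = 1400, ...) {
  reader_profile(capacity_by_time = stats::setNames(caps, grid_times),
                 required_vrt_ms = vrt, ...)
}

# A random lapse-free reader whose parameters lie on the protocol grids and
# inside the staircase's resolvable range: capacities between the 3-letter
# start and the 8-letter cap; VRT on the 50 ms grid, at or above the maximum
# fixation time (the bisection's floor is the presentation time) and below
# the generous allowance.
random_grid_profile <- function() {
  start <- sample(3:6, 1)
  caps <- cumsum(c(start, sample(0:1, 5, replace = TRUE)))
  caps <- pmin(caps, 8L)
  make_reader(caps, vrt = 50 * sample(10:68, 1))  # 500..3400 ms
}

# Random monotone boolean oracle on n conditions: pass iff the met set
# contains one of a few random generator sets.
random_monotone_oracle <- function(conds) {
  k <- sample(1:4, 1)
  terms <- lapply(seq_len(k), function(i) {
    sample(conds, sample(seq_along(conds), 1))
  })
  oracle_function(function(met) {
    any(vapply(terms, function(tt) all(tt %in% met), logical(1)))
  })
}

# Minimal reading_session wrapper around hand-made trial records.
make_session <- function(records, mode = "unguided") {
  structure(
    list(mode = mode, records = records, total_segments = nrow(records),
         total_errors = sum(!records$correct),
         total_time_ms = 0, regressions = 0L),
    class = "reading_session"
  )
}

# An external responder that always fails and never spells correctly.
hopeless_responder <- list(
  respond = function(item, presentation_ms, allowed_vrt_ms) FALSE,
  spell = function(item, presentation_ms) FALSE
)

toy_lexicon <- c(
  "haus", "maus", "baum", "raum", "laut", "haut", "brot", "rot", "boot",
  "tor", "tag", "sag", "lag", "mag", "wal", "tal", "mal", "hal", "hund",
  "mund", "bund", "rund", "wund", "kind", "wind", "rind", "band", "hand",
  "land", "sand", "wand", "gans", "hans", "lese", "nase", "vase", "base",
  "rabe", "gabe", "habe", "lobe", "robe", "tube", "stube", "grube",
  "truhe", "ruhe", "kuhle", "mulde", "halde"
)
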