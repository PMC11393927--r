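#' Condition universe
#'
#' The ordered set of conditions under which a person can read flawlessly,
#' with optional human-readable labels. Exhaustive analysis enumerates all
#' 2^n subsets, so the universe is capped at 20 conditions.
#'
#' @param conditions character vector of unique condition identifiers.
#' @param labels optional named character vector mapping identifiers to
#'   descriptions.
#' @return a `condition_universe`.
#' @export
condition_universe <- function(conditions, labels = NULL) {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop_precondition("condition identifiers must be unique")
  if (length(conditions) > 20L)
    stop_precondition("exhaustive mode supports at most 20 conditions")
  if (length(conditions) == 0L) stop_precondition("need at least one condition")
  structure(list(conditions = conditions,
                 labels = labels %||% stats::setNames(conditions, conditions)),
            class = "condition_universe")
}

#' Outcome oracles over condition subsets
#'
#' An oracle maps the set of MET conditions to `"pass"` (the person reads at
#' the required level) or `"fail"`. `oracle_function()` wraps an R function
#' of a character vector; `oracle_truth_table()` takes an explicit table;
#' `oracle_formula()` builds the canonical monotone form: pass iff all
#' `gamma` conditions are met and each `lambda` set has at least one met
#' member. A numeric-score function can be thresholded at performance level
#' `level` (scores >= level count as pass).
#'
#' @param fn function of a character vector of met conditions returning
#'   `"pass"`/`"fail"`, a logical, or (with `level`) a number.
#' @param level optional numeric threshold turning a score into pass/fail.
#' @return a function usable as an oracle (character vector -> "pass"/"fail").
#' @export
oracle_function <- function(fn, level = NULL) {
  force(fn); force(level)
  function(met) {
    out <- fn(met)
    if (!is.null(level) && is.numeric(out)) out <- out >= level
    if (is.logical(out)) out <- if (isTRUE(out)) "pass" else "fail"
    if (!out %in% c("pass", "fail"))
      stop_precondition("oracle must return 'pass' or 'fail'")
    out
  }
}

#' @rdname oracle_function
#' @param table list of entries `list(met = <character>, outcome = "pass"|"fail")`
#'   covering every subset that will be queried.
#' @export
oracle_truth_table <- function(table) {
  key <- function(met) paste0("S:", paste(sort(unique(met)), collapse = "\r"))
  map <- new.env(parent = emptyenv())
  for (entry in table) assign(key(entry$met), entry$outcome, envir = map)
  function(met) {
    out <- get0(key(met), envir = map)
    if (is.null(out)) stop_precondition("truth table has no entry for subset {",
                                        paste(met, collapse = ", "), "}")
    out
  }
}

#' @rdname oracle_function
#' @param gamma character vector of irreplaceable necessary conditions.
#' @param lambda list of character vectors, the interchangeable sets.
#' @export
oracle_formula <- function(gamma = character(), lambda = list()) {
  force(gamma); force(lambda)
  function(met) {
    ok <- all(gamma %in% met) &&
      all(vapply(lambda, function(s) any(s %in% met), logical(1)))
    if (ok) "pass" else "fail"
  }
}

# All subsets of a universe as a list of character vectors (bitmask order).
all_subsets <- function(conditions) {
  n <- length(conditions)
  lapply(0:(2^n - 1L), function(mask) conditions[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
}

#' Check that an oracle is monotone
#'
#' Adding a met condition must never turn a pass into a fail. Verified
#' exhaustively: for every subset S and condition x not in S, if S passes
#' then S + x passes.
#'
#' @param universe a [condition_universe()].
#' @param oracle an oracle function (see [oracle_function()]).
#' @return list with `monotone` (logical) and, when violated, `witness`, a
#'   list of two subsets `smaller`/`larger` with pass -> fail.
#' @export
check_monotone <- function(universe, oracle) {
  stopifnot(inherits(universe, "condition_universe"))
  conds <- universe$conditions
  for (s in all_subsets(conds)) {
    if (oracle(s) != "pass") next
    for (x in setdiff(conds, s)) {
      if (oracle(c(s, x)) == "fail")
        return(list(monotone = FALSE,
                    witness = list(smaller = s, larger = c(s, x))))
    }
  }
  list(monotone = TRUE, witness = NULL)
}

#' Classify conditions as irreplaceable-necessary, replaceable-sufficient or
#' superfluous
#'
#' Computes, by exhaustive enumeration, the minimal condition sets at least
#' one member of which must be met for a pass (the prime implicates of the
#' monotone pass-function): a set C is an implicate iff the full universe
#' minus C fails. Singleton implicates are the irreplaceable necessary
#' conditions (gamma); multi-element implicates are the candidate
#' interchangeable sets (lambda); conditions in no implicate are superfluous.
#' The classification is `canonical` iff the lambda sets are pairwise
#' disjoint and the reconstruction "all of gamma met AND at least one member
#' of every lambda set met" agrees with the oracle on every subset. (The
#' conjunction of all prime implicates always reproduces a monotone oracle,
#' so a non-canonical result normally stems from overlapping lambda sets; a
#' `witness` subset is reported only if a genuine disagreement exists.)
#'
#' @param universe a [condition_universe()].
#' @param oracle a monotone oracle; non-monotone oracles are rejected with
#'   the violating pair.
#' @return a `causal_classification` with fields `gamma`, `lambda_sets`,
#'   `superfluous`, `canonical`, `witness`, `universe`.
#' @examples
#' u <- condition_universe(c("size5mm", "time400ms", "bg_white",
#'                           "bg_yellow", "bg_blue"))
#' orc <- oracle_formula(lambda = list(c("size5mm", "time400ms"),
#'                                     c("bg_white", "bg_yellow", "bg_blue")))
#' extract_classification(u, orc)
#' @export
extract_classification <- function(universe, oracle) {
  stopifnot(inherits(universe, "condition_universe"))
  mono <- check_monotone(universe, oracle)
  if (!mono$monotone)
    stop_precondition("oracle is not monotone: {",
                      paste(mono$witness$smaller, collapse = ","),
                      "} passes but {",
                      paste(mono$witness$larger, collapse = ","), "} fails")
  conds <- universe$conditions
  subsets <- all_subsets(conds)
  # implicates: C such that oracle(universe \ C) fails
  implicates <- Filter(function(C) {
    length(C) > 0L && oracle(setdiff(conds, C)) == "fail"
  }, subsets)
  is_minimal <- vapply(implicates, function(C) {
    !any(vapply(implicates, function(D) {
      length(D) < length(C) && all(D %in% C)
    }, logical(1)))
  }, logical(1))
  prime <- implicates[is_minimal]

  sizes <- lengths(prime)
  gamma <- sort(unlist(prime[sizes == 1L]) %||% character())
  lambda_sets <- lapply(prime[sizes > 1L], sort)
  in_clause <- unique(unlist(prime))
  superfluous <- sort(setdiff(conds, in_clause))

  disjoint <- TRUE
  multi <- lambda_sets
  if (length(multi) > 1L) {
    pooled <- unlist(multi)
    disjoint <- !anyDuplicated(pooled)
  }
  if (length(gamma) && length(multi) && any(gamma %in% unlist(multi)))
    disjoint <- FALSE

  reconstruction <- oracle_formula(gamma = gamma, lambda = lambda_sets)
  witness <- NULL
  agrees <- TRUE
  for (s in subsets) {
    if (reconstruction(s) != oracle(s)) {
      agrees <- FALSE
      witness <- sort(s)
      break
    }
  }
  canonical <- disjoint && agrees

  structure(
    list(gamma = as.character(gamma),
         lambda_sets = lambda_sets,
         superfluous = as.character(superfluous),
         canonical = canonical,
         witness = witness,
         universe = universe),
    class = "causal_classification"
  )
}

#' @export
print.causal_classification <- function(x, ...) {
  fmt_set <- function(s) paste0("{", paste(s, collapse = ", "), "}")
  cat("<causal_classification>\n")
  cat("  irreplaceable necessary (gamma):", fmt_set(x$gamma), "\n")
  if (length(x$lambda_sets))
    cat("  interchangeable sets (lambda):",
        paste(vapply(x$lambda_sets, fmt_set, character(1)), collapse = " "), "\n")
  cat("  superfluous:", fmt_set(x$superfluous), "\n")
  cat("  canonical:", x$canonical, "\n")
  if (!is.null(x$witness))
    cat("  witness (disagreeing subset):", fmt_set(x$witness), "\n")
  invisible(x)
}

#' Attribute causes of reading failure under given met conditions
#'
#' Applies the causal definitions to a canonical classification: every unmet
#' irreplaceable necessary condition is an irreplaceable necessary cause;
#' every interchangeable set none of whose members is met is a replaceable
#' sufficient cause (reported at set level); unmet superfluous conditions are
#' not causes. Reading is predicted to fail iff at least one cause is
#' reported.
#'
#' @param classification a canonical [extract_classification()] result.
#' @param met_conditions character vector of met condition identifiers.
#' @return a `cause_report` with `causes` (data.frame: what, category) and
#'   `predicted` (`"pass"`/`"fail"`).
#' @export
diagnose_causes <- function(classification, met_conditions) {
  stopifnot(inherits(classification, "causal_classification"))
  if (!isTRUE(classification$canonical))
    stop_precondition("cause attribution requires a canonical classification")
  met <- as.character(met_conditions)
  unknown <- setdiff(met, classification$universe$conditions)
  if (length(unknown))
    stop_precondition("conditions outside the declared universe: ",
                      paste(unknown, collapse = ", "))
  rows <- list()
  for (g in classification$gamma) {
    if (!(g %in% met))
      rows[[length(rows) + 1L]] <- data.frame(
        what = g, category = "irreplaceable_necessary_cause")
  }
  for (lam in classification$lambda_sets) {
    if (!any(lam %in% met))
      rows[[length(rows) + 1L]] <- data.frame(
        what = paste(lam, collapse = "|"),
        category = "replaceable_sufficient_cause")
  }
  for (s in classification$superfluous) {
    if (!(s %in% met))
      rows[[length(rows) + 1L]] <- data.frame(what = s, category = "not_a_cause")
  }
  causes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(what = character(), category = character())
  real <- causes$category != "not_a_cause"
  structure(
    list(causes = causes,
         predicted = if (any(real)) "fail" else "pass"),
    class = "cause_report"
  )
}

#' @export
print.cause_report <- function(x, ...) {
  cat("<cause_report> predicted:", x$predicted, "\n")
  if (nrow(x$causes)) print(x$causes) else cat("  no causes\n")
  invisible(x)
}

#' Read an oracle description from JSON
#'
#' Two schemas are accepted: an explicit truth table
#' `{"conditions": [...], "table": [{"met": [...], "outcome": "pass"}, ...]}`
#' or a formula `{"conditions": [...], "gamma": [...], "lambda": [[...], ...]}`.
#'
#' @param path JSON file path.
#' @return list with `universe` and `oracle`.
#' @export
read_oracle <- function(path) {
  x <- jsonlite::read_json(path)
  conds <- unlist(x$conditions)
  if (is.null(conds)) stop_precondition("oracle JSON must declare 'conditions'")
  universe <- condition_universe(conds)
  oracle <- if (!is.null(x$table)) {
    oracle_truth_table(lapply(x$table, function(e)
      list(met = unlist(e$met) %||% character(), outcome = e$outcome)))
  } else if (!is.null(x$gamma) || !is.null(x$lambda)) {
    oracle_formula(gamma = unlist(x$gamma) %||% character(),
                   lambda = lapply(x$lambda %||% list(), unlist))
  } else {
    stop_precondition("oracle JSON must contain either 'table' or 'gamma'/'lambda'")
  }
  list(universe = universe, oracle = oracle)
}
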