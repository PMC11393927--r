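worked_universe <- function() {
  condition_universe(c("size5mm", "time400ms", "bg_white", "bg_yellow", "bg_blue"))
}
worked_oracle <- function() {
  oracle_function(function(met) {
    any(c("size5mm", "time400ms") %in% met) &&
      any(c("bg_white", "bg_yellow", "bg_blue") %in% met)
  })
}

test_that("monotonicity checking finds violations with a witness", {
  u <- condition_universe(c("a", "b", "c"))
  expect_true(check_monotone(u, oracle_function(function(met) TRUE))$monotone)
  parity <- oracle_function(function(met) length(met) %% 2 == 0)
  res <- check_monotone(u, parity)
  expect_false(res$monotone)
  expect_equal(parity(res$witness$smaller), "pass")
  expect_equal(parity(res$witness$larger), "fail")
  expect_true(check_monotone(worked_universe(), worked_oracle())$monotone)
})

test_that("the letter-size/background example classifies into two interchangeable sets", {
  cls <- extract_classification(worked_universe(), worked_oracle())
  expect_equal(cls$gamma, character(0))
  expect_equal(cls$superfluous, character(0))
  expect_true(cls$canonical)
  sets <- lapply(cls$lambda_sets, sort)
  expect_length(sets, 2)
  expect_true(any(vapply(sets, function(s)
    setequal(s, c("size5mm", "time400ms")), logical(1))))
  sizes <- sort(lengths(sets))
  expect_equal(sizes, c(2, 3))
  expect_true(any(vapply(sets, function(s)
    setequal(s, c("bg_white", "bg_yellow", "bg_blue")), logical(1))))
})

test_that("a pure conjunction yields only irreplaceable necessary conditions", {
  u <- condition_universe(c("c1", "c2", "c3"))
  orc <- oracle_formula(gamma = c("c1", "c2", "c3"))
  cls <- extract_classification(u, orc)
  expect_equal(sort(cls$gamma), c("c1", "c2", "c3"))
  expect_length(cls$lambda_sets, 0)
  expect_equal(cls$superfluous, character(0))
  expect_true(cls$canonical)
})

test_that("conditions outside every minimal clause are superfluous", {
  u <- condition_universe(c("a", "b", "x"))
  orc <- oracle_formula(gamma = "a", lambda = list())
  cls <- extract_classification(u, orc)
  expect_equal(cls$gamma, "a")
  expect_equal(sort(cls$superfluous), c("b", "x"))
  expect_true(cls$canonical)
})

test_that("classification reconstructs random monotone oracles subset by subset", {
  set.seed(17)
  conds_pool <- letters[1:6]
  for (i in 1:200) {
    n <- sample(2:6, 1)
    conds <- conds_pool[1:n]
    u <- condition_universe(conds)
    orc <- random_monotone_oracle(conds)
    cls <- extract_classification(u, orc)
    rebuilt <- oracle_formula(gamma = cls$gamma, lambda = cls$lambda_sets)
    subsets <- lapply(0:(2^n - 1), function(m) conds[bitwAnd(m, 2^(0:(n - 1))) > 0])
    if (cls$canonical) {
      for (s in subsets) expect_equal(rebuilt(s), orc(s))
      expect_null(cls$witness)
    } else if (!is.null(cls$witness)) {
      expect_false(rebuilt(cls$witness) == orc(cls$witness))
    } else {
      # non-canonical only because multi-element clauses overlap
      pooled <- unlist(cls$lambda_sets)
      expect_true(anyDuplicated(pooled) > 0)
    }
    # gamma, lambdas and superfluous partition the universe
    expect_true(setequal(c(cls$gamma, unlist(cls$lambda_sets), cls$superfluous),
                         conds))
    expect_true(all(lengths(cls$lambda_sets) >= 2))
  }
})

test_that("classification is invariant under permuting the condition order", {
  conds <- c("p", "q", "r", "s")
  orc <- oracle_formula(gamma = "p", lambda = list(c("q", "r")))
  a <- extract_classification(condition_universe(conds), orc)
  b <- extract_classification(condition_universe(rev(conds)), orc)
  expect_equal(a$gamma, b$gamma)
  expect_true(setequal(unlist(a$lambda_sets), unlist(b$lambda_sets)))
  expect_equal(a$superfluous, b$superfluous)
  expect_equal(a$canonical, b$canonical)
})

test_that("non-monotone oracles are rejected with the violating pair", {
  u <- condition_universe(c("a", "b"))
  parity <- oracle_function(function(met) length(met) %% 2 == 0)
  expect_error(extract_classification(u, parity), "not monotone")
})

test_that("cause attribution follows the three-way definition", {
  cls <- extract_classification(worked_universe(), worked_oracle())
  # all required sets satisfied: no causes, predicted pass
  rep0 <- diagnose_causes(cls, c("time400ms", "bg_white"))
  expect_equal(rep0$predicted, "pass")
  expect_equal(nrow(rep0$causes[rep0$causes$category != "not_a_cause", ]), 0)
  # no background met: one replaceable sufficient cause at set level
  rep1 <- diagnose_causes(cls, c("size5mm", "time400ms"))
  expect_equal(rep1$predicted, "fail")
  real <- rep1$causes[rep1$causes$category != "not_a_cause", ]
  expect_equal(nrow(real), 1)
  expect_equal(real$category, "replaceable_sufficient_cause")
  expect_true(setequal(strsplit(real$what, "|", fixed = TRUE)[[1]],
                       c("bg_white", "bg_yellow", "bg_blue")))
  # everything met: zero causes
  rep2 <- diagnose_causes(cls, worked_universe()$conditions)
  expect_equal(rep2$predicted, "pass")
})

test_that("unmet superfluous conditions are never causes", {
  u <- condition_universe(c("a", "x"))
  cls <- extract_classification(u, oracle_formula(gamma = "a"))
  rep <- diagnose_causes(cls, "a")  # x unmet
  expect_equal(rep$predicted, "pass")
  expect_true(all(rep$causes$category == "not_a_cause"))
})

test_that("cause reports agree with the oracle outcome on every subset", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    conds <- letters[1:n]
    u <- condition_universe(conds)
    orc <- random_monotone_oracle(conds)
    cls <- extract_classification(u, orc)
    if (!cls$canonical) next
    subsets <- lapply(0:(2^n - 1), function(m) conds[bitwAnd(m, 2^(0:(n - 1))) > 0])
    for (s in subsets) {
      rep <- diagnose_causes(cls, s)
      expect_equal(rep$predicted, orc(s))
    }
  }
})

test_that("removing and restoring a gamma condition flips the outcome", {
  u <- condition_universe(c("fix_time", "letter_count", "vrt"))
  orc <- oracle_formula(gamma = c("fix_time", "letter_count", "vrt"))
  cls <- extract_classification(u, orc)
  full <- u$conditions
  expect_equal(diagnose_causes(cls, full)$predicted, "pass")
  expect_equal(diagnose_causes(cls, setdiff(full, "vrt"))$predicted, "fail")
  expect_equal(diagnose_causes(cls, full)$predicted, "pass")
})

test_that("oracles load from truth-table and formula JSON", {
  tt <- list(conditions = c("a", "b"),
             table = list(list(met = list("a", "b"), outcome = "pass"),
                          list(met = list("a"), outcome = "pass"),
                          list(met = list("b"), outcome = "fail"),
                          list(met = list(), outcome = "fail")))
  f1 <- tempfile(fileext = ".json")
  jsonlite::write_json(tt, f1, auto_unbox = TRUE)
  spec1 <- read_oracle(f1)
  cls1 <- extract_classification(spec1$universe, spec1$oracle)
  expect_equal(cls1$gamma, "a")
  expect_equal(cls1$superfluous, "b")

  ff <- list(conditions = c("a", "b", "c"),
             gamma = list("a"), lambda = list(list("b", "c")))
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(ff, f2, auto_unbox = TRUE)
  spec2 <- read_oracle(f2)
  cls2 <- extract_classification(spec2$universe, spec2$oracle)
  expect_equal(cls2$gamma, "a")
  expect_length(cls2$lambda_sets, 1)
  expect_true(setequal(cls2$lambda_sets[[1]], c("b", "c")))
})
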