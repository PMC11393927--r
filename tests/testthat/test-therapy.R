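test_that("error reduction is the plain percentage decrease", {
  expect_equal(error_reduction(30, 9), 70)
  expect_equal(error_reduction(10, 10), 0)
  expect_equal(round(error_reduction(12, 4), 2), 66.67)
  expect_lt(error_reduction(10, 15), 0)  # deterioration allowed, capped at 100 above
  expect_error(error_reduction(0, 5), "positive")
})

test_that("Hedges g matches hand-computed values and its symmetries", {
  expect_equal(hedges_g(c(10, 12, 14), c(2, 4, 6)), 3.2)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(hedges_g(c(2, 4, 6), c(10, 12, 14)), -3.2)
  expect_error(hedges_g(c(1, 1, 1), c(1, 1, 1)), "variance")
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
})

test_that("fully compliant lapse-free readers make zero guided errors", {
  r <- make_reader(caps = c(3, 4, 4, 5, 5, 6), vrt = 1400,
                   compliance = 1, lapse_rate = 0)
  text <- synthetic_text(300, rng_seed = 8)
  s <- simulate_guided(r, text, capacity = 6, fixation_ms = 500,
                       allowed_vrt_ms = 1400, rng_seed = 1)
  expect_equal(s$total_errors, 0)
  expect_true(all(s$records$attempts == 1))
})

test_that("guided parameters must lie on the protocol grids", {
  r <- make_reader()
  expect_error(simulate_guided(r, "haus", 4, fixation_ms = 275,
                               allowed_vrt_ms = 1400), "grid")
  expect_error(simulate_guided(r, "haus", 4, fixation_ms = 300,
                               allowed_vrt_ms = 1425), "multiple")
})

test_that("failed segments are re-attempted before the next segment appears", {
  r <- make_reader(caps = c(3, 4, 4, 5, 5, 6), vrt = 1400,
                   compliance = 0.6, lapse_rate = 0)
  text <- synthetic_text(400, rng_seed = 12)
  s <- simulate_guided(r, text, capacity = 6, fixation_ms = 500,
                       allowed_vrt_ms = 1400, rng_seed = 2)
  # non-compliant first attempts fail (premature pronunciation) and are
  # retried until correct: every segment ends up read, extra attempts exist
  expect_true(any(s$records$attempts > 1))
  expect_true(all(s$records$attempts < 25))
  expect_equal(s$total_errors, sum(!s$records$correct))
  expect_gte(s$total_segments, nrow(s$records))
})

test_that("guided reading beats unguided reading for every simulated reader", {
  set.seed(6)
  cohort <- sample_cohort(10, "low_vrt")
  text <- synthetic_text(400)
  inv <- cluster_inventory("de")
  for (reader in cohort) {
    ung <- simulate_unguided(reader, text, inv)
    cap <- max(reader$capacity_by_time)
    fix <- as.numeric(names(reader$capacity_by_time))[
      which(reader$capacity_by_time == cap)[1]]
    vrt <- 50 * ceiling(reader$required_vrt_ms / 50)
    gui <- simulate_guided(reader, text, cap, fix, vrt, inv)
    expect_lt(gui$total_errors, ung$total_errors)
  }
})

test_that("self-segmenting readers are slow but accurate", {
  r <- make_reader(caps = c(3, 3, 3, 3, 3, 4), vrt = 1200, lapse_rate = 0,
                   strategy = "staircase_segments")
  text <- synthetic_text(300, rng_seed = 21)
  s <- simulate_unguided(r, text, rng_seed = 3)
  expect_equal(s$total_errors, 0)  # lapse-free: mechanism errors absent
  n_words <- length(strsplit(text, " ")[[1]])
  expect_gt(s$total_time_ms, n_words * (250 + 30))  # slower than whole-word sweeps
  # same reader, whole-word strategy: many errors
  r2 <- make_reader(caps = c(3, 3, 3, 3, 3, 4), vrt = 1200, lapse_rate = 0,
                    strategy = "whole_word")
  s2 <- simulate_unguided(r2, text, rng_seed = 3)
  expect_gt(s2$total_errors, 0)
  expect_gt(s$total_time_ms, s2$total_time_ms)
})

test_that("interspersed regressions never change correctness", {
  r <- make_reader(caps = rep(4, 6), vrt = 900, lapse_rate = 0,
                   strategy = "staircase_segments")
  text <- synthetic_text(250, rng_seed = 30)
  errs <- integer(10); regs <- integer(10)
  for (s in 1:10) {
    ses <- simulate_unguided(r, text, rng_seed = s)
    errs[s] <- ses$total_errors
    regs[s] <- ses$regressions
  }
  expect_true(all(errs == 0))      # outcomes identical across RNG streams
  expect_true(any(regs > 0))       # while regressions do occur
})

test_that("hypermetric saccades without correction create unseen letters and errors", {
  r <- make_reader(caps = rep(4, 6), vrt = 900, lapse_rate = 0,
                   strategy = "hypermetric_no_correction")
  text <- synthetic_text(300, rng_seed = 14)
  s <- simulate_unguided(r, text, rng_seed = 4)
  expect_gt(s$total_errors, 0)
  r_ok <- make_reader(caps = rep(4, 6), vrt = 900, lapse_rate = 0,
                      strategy = "staircase_segments")
  s_ok <- simulate_unguided(r_ok, text, rng_seed = 4)
  expect_gt(s$total_errors, s_ok$total_errors)
})

test_that("letter-by-letter readers crawl through the text", {
  r <- make_reader(caps = rep(5, 6), vrt = 800, lapse_rate = 0,
                   strategy = "letter_by_letter")
  text <- "haus maus baum"
  s <- simulate_unguided(r, text, rng_seed = 2)
  expect_equal(s$total_errors, 0)
  expect_gte(s$total_time_ms, 12 * 250)  # one fixation per letter
})

test_that("error positions tally into a uniform profile", {
  single <- make_session(data.frame(
    unit = "abcde", attempted_length = 5L, fixation_ms = 250,
    allowed_vrt_ms = 1000, correct = FALSE, error_position = 0L, attempts = 1L))
  prof <- error_position_profile(single)
  expect_equal(unname(prof$counts), c(1, 0, 0, 0, 0))

  r <- make_reader(caps = rep(3, 6), vrt = 300)
  set.seed(9)
  outs <- replicate(1e4, recognize(r, "blirk", 500, 400)$error_position)
  recs <- data.frame(unit = "blirk", attempted_length = 5L, fixation_ms = 500,
                     allowed_vrt_ms = 400, correct = FALSE,
                     error_position = outs, attempts = 1L)
  prof2 <- error_position_profile(make_session(recs))
  expect_gt(prof2$p_value, 0.001)
  # no excess at the word's last (singly flanked) letter
  counts <- prof2$counts
  expect_lte(counts[["4"]], mean(counts[c("1", "2", "3")]) + 200)
  expect_error(error_position_profile(make_session(recs[0, ])), "error")
})

test_that("the cohort experiment reports consistent pooled quantities", {
  out <- run_therapy_experiment(n_readers = 8, text = synthetic_text(300, rng_seed = 2),
                                rng_seed = 3)
  expect_equal(out$errors_unguided, sum(out$per_reader$errors_unguided))
  expect_equal(out$errors_guided, sum(out$per_reader$errors_guided))
  expect_equal(out$reduction_percent,
               error_reduction(out$errors_unguided, out$errors_guided))
  expect_true(all(out$per_reader$errors_guided <=
                    out$per_reader$errors_unguided))
  expect_gt(out$hedges_g, 0)
  # reproducible from the seed
  out2 <- run_therapy_experiment(n_readers = 8,
                                 text = synthetic_text(300, rng_seed = 2),
                                 rng_seed = 3)
  expect_equal(out$per_reader, out2$per_reader)
})
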