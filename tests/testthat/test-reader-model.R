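test_that("visible window masks the blind hemifield and compensation restores it", {
  right <- visual_field_defect("right", TRUE, "none")
  expect_equal(visible_window(6, 2, right), 0:2)
  expect_equal(visible_window(6, 2, visual_field_defect("right", TRUE, "gaze_to_end")),
               0:5)
  expect_equal(visible_window(6, 4, visual_field_defect("left", TRUE, "gaze_to_beginning")),
               0:5)
  expect_equal(visible_window(5, 2, NULL), 0:4)
  # defects sparing the fovea leave the word visible
  expect_equal(visible_window(6, 2, visual_field_defect("right", FALSE, "none")), 0:5)
  expect_error(visible_window(5, 5, right), "fixation_index")
  expect_error(visual_field_defect("left", TRUE, "gaze_to_end"), "right")
  expect_error(visual_field_defect("right", TRUE, "gaze_to_beginning"), "left")
})

test_that("compensated windows are supersets of uncompensated ones", {
  for (side in c("left", "right")) {
    comp <- if (side == "right") "gaze_to_end" else "gaze_to_beginning"
    d0 <- visual_field_defect(side, TRUE, "none")
    d1 <- visual_field_defect(side, TRUE, comp)
    for (len in 1:12) {
      for (fix in 0:(len - 1)) {
        expect_true(all(visible_window(len, fix, d0) %in%
                          visible_window(len, fix, d1)))
      }
    }
  }
})

test_that("recognition requires capacity, a complete window, and enough verbal reaction time", {
  r <- make_reader()  # ceiling 6 at 500 ms, required VRT 1400
  expect_true(recognize(r, "blirke", 500, 1500, rng_seed = 1)$correct)
  expect_false(recognize(r, "blirke", 500, 1200, rng_seed = 1)$correct)
  expect_false(recognize(r, "blirkes", 500, 1500, rng_seed = 1)$correct) # 7 > 6
  expect_false(recognize(r, "blirke", 250, 1500, rng_seed = 1)$correct)  # 6 > 3
  # no stochastic term active: always correct
  expect_true(all(replicate(200, recognize(r, "bli", 250, 1500)$correct)))
  # deterministic given the seed
  o1 <- recognize(r, "blirkes", 500, 1500, rng_seed = 42)
  o2 <- recognize(r, "blirkes", 500, 1500, rng_seed = 42)
  expect_identical(o1, o2)
  expect_error(recognize(r, "", 500, 1500), "letter")
})

test_that("VRT-only failures are not letter-level errors; capacity failures are", {
  r <- make_reader()
  out <- recognize(r, "blirke", 500, 1000, rng_seed = 1)
  expect_false(out$correct)
  expect_true(is.na(out$error_position))
  out2 <- recognize(r, "blirkes", 500, 1500, rng_seed = 1)
  expect_false(out2$correct)
  expect_true(out2$error_position %in% 0:6)
})

test_that("a right foveal defect without compensation misses word endings", {
  r <- make_reader(field_defect = visual_field_defect("right", TRUE, "none"))
  out <- recognize(r, "bli", 500, 1500, rng_seed = 1)
  expect_false(out$correct)
  expect_true(out$error_position > (3 - 1) %/% 2)  # an unseen trailing letter
})

test_that("lapse frequency matches the configured rate", {
  r <- make_reader(lapse_rate = 0.04)
  n <- 1e4
  set.seed(11)
  errs <- sum(!replicate(n, recognize(r, "bli", 500, 1500)$correct))
  p <- 0.04
  expect_lt(abs(errs / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("capacity-driven error positions are uniform over the word", {
  r <- make_reader(caps = rep(3, 6), vrt = 300)
  set.seed(7)
  pos <- replicate(1e4, recognize(r, "blirk", 500, 400)$error_position)
  counts <- tabulate(pos + 1L, nbins = 5)
  expect_equal(sum(counts), 1e4)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("grapheme confusions produce letter-level errors at the confusable letter", {
  r <- make_reader(grapheme_confusions = c("pq", "bd"))
  set.seed(3)
  outs <- replicate(500, recognize(r, "lap", 500, 1500)$correct)
  frac <- mean(!outs)
  expect_gt(frac, 0.4); expect_lt(frac, 0.6)  # one confusable letter at p = 0.5
  bad <- recognize(r, "lap", 500, 1500, rng_seed = 2)
  if (!bad$correct) expect_equal(bad$error_position, 2L)
  expect_true(all(replicate(100, recognize(r, "lass", 500, 1500)$correct)))
})

test_that("reader profile invariants are enforced", {
  expect_error(make_reader(caps = c(4, 3, 4, 5, 5, 6)), "monotone")
  expect_error(make_reader(caps = rep(9, 6)), "0..8")
  expect_error(make_reader(vrt = 0), "positive")
  expect_error(make_reader(lapse_rate = 0.2), "lapse")
  expect_error(make_reader(compliance = 1.5), "compliance")
})

test_that("cohort sampler reproduces the study population", {
  co <- sample_cohort(10000, "low_vrt", rng_seed = 1)
  vrts <- vapply(co, function(r) r$required_vrt_ms, numeric(1))
  # analytic mean of N(1316, 712^2) truncated below at 200 ms
  a <- (200 - 1316) / 712
  tmean <- 1316 + 712 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(vrts) - tmean), 3 * sd(vrts) / sqrt(length(vrts)))
  expect_true(all(vrts > 200))

  ceilings <- vapply(co, function(r) max(r$capacity_by_time), numeric(1))
  expect_true(all(ceilings %in% 3:6))
  expect_lt(abs(mean(ceilings == 6) - 0.1), 0.02)  # "few" at ceiling six

  co500 <- sample_cohort(500, rng_seed = 1)
  expect_equal(max(vapply(co500, function(r) max(r$capacity_by_time), numeric(1))), 6)

  one <- sample_cohort(1, "high_vrt", rng_seed = 9)[[1]]
  expect_s3_class(one, "reader_profile")
  expect_false(is.unsorted(one$capacity_by_time))
  expect_error(sample_cohort(0), "positive")
})

test_that("profiles round-trip through JSON, YAML and JSONL", {
  r <- sample_cohort(1, "low_vrt", rng_seed = 4)[[1]]
  r$field_defect <- visual_field_defect("right", TRUE, "gaze_to_end")
  for (ext in c(".json", ".yaml")) {
    tmp <- tempfile(fileext = ext)
    write_profile(r, tmp)
    r2 <- read_profile(tmp)
    expect_equal(r2$capacity_by_time, r$capacity_by_time)
    expect_equal(r2$required_vrt_ms, r$required_vrt_ms)
    expect_equal(r2$field_defect$compensation, "gaze_to_end")
    expect_equal(r2$compliance, r$compliance)
  }
  co <- sample_cohort(5, rng_seed = 2)
  tmp <- tempfile(fileext = ".jsonl")
  write_cohort(co, tmp)
  co2 <- read_cohort(tmp)
  expect_length(co2, 5)
  expect_equal(co2[[3]]$capacity_by_time, co[[3]]$capacity_by_time)
  expect_equal(co2[[3]]$required_vrt_ms, co[[3]]$required_vrt_ms)
})
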