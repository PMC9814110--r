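test_that("EC3 is interpolated linearly between the bracketing pair", {
  expect_equal(ec3_from_study(make_si_series(c(0.5, 1, 2), c(1, 3, 6)))$value,
               1)  # exact hit
  est <- ec3_from_study(make_si_series(c(0.1, 0.3), c(2, 5)))
  expect_equal(est$value, 0.1 + (3 - 2) / (5 - 2) * 0.2)
  expect_identical(est$method, "interpolated")
  expect_true(est$accepted)
  # the lowest bracketing pair wins in a non-monotone series
  est <- ec3_from_study(make_si_series(c(1, 2, 4, 8), c(1, 4, 2, 6)))
  expect_equal(est$value, 1 + (3 - 1) / (4 - 1) * 1)
})

test_that("EC3 above the tested range is extrapolated from the top points", {
  est <- ec3_from_study(make_si_series(c(1, 5, 25), c(1.1, 1.2, 1.3)))
  expect_identical(est$method, "extrapolated")
  # closed-form line through the two highest points
  expect_equal(est$value, 25 + (3 - 1.3) / ((1.3 - 1.2) / (25 - 5)))
})

test_that("EC3 below the tested range is extrapolated from the bottom points", {
  est <- ec3_from_study(make_si_series(c(0.5, 1, 2), c(5, 8, 12)))
  expect_identical(est$method, "extrapolated")
  expect_equal(est$value, 0.5 + (3 - 5) / ((8 - 5) / (1 - 0.5)))
})

test_that("flat or declining sub-threshold curves are negative calls", {
  est <- ec3_from_study(make_si_series(c(1, 5, 25), c(1.5, 1.4, 1.2)))
  expect_true(est$negative)
  expect_true(is.na(est$value))
  expect_identical(ghs_classify(est$value), "NC")
})

test_that("the extrapolation screen applies each criterion with its reason", {
  # interpolated estimates pass through unchanged
  s <- make_si_series(c(0.1, 0.3), c(2, 5))
  est <- ec3_from_study(s)
  expect_identical(ryan_screen(est, s), est)

  # lowest SI of exactly 5 fails the strict '< 5' criterion
  s <- make_si_series(c(0.5, 1, 2), c(5, 8, 12))
  scr <- ryan_screen(ec3_from_study(s), s)
  expect_false(scr$accepted)
  expect_identical(scr$rejection_reasons, "lowest_si_ge_5")

  # an acceptable downward extrapolation passes all three criteria
  s <- make_si_series(c(0.5, 1, 2), c(4, 6, 10))
  scr <- ryan_screen(ec3_from_study(s), s)
  expect_true(scr$accepted)
  expect_equal(scr$value, 0.25)

  # extrapolated EC3 more than 10-fold beyond the closest tested concentration
  s <- make_si_series(c(1, 5, 25), c(1.1, 1.2, 1.3))
  scr <- ryan_screen(ec3_from_study(s), s)
  expect_false(scr$accepted)
  expect_identical(scr$rejection_reasons, "extrapolation_gt_10x")

  # slope ratio above 2 (accelerating top end) fails
  s <- make_si_series(c(1, 2, 3), c(1.0, 1.2, 2.6))
  scr <- ryan_screen(ec3_from_study(s), s)
  expect_true("slope_ratio_fail" %in% scr$rejection_reasons)

  # two-concentration studies cannot be screened and are rejected
  s <- make_si_series(c(1, 2), c(1.0, 2.0))
  scr <- ryan_screen(ec3_from_study(s), s)
  expect_true("slope_ratio_fail" %in% scr$rejection_reasons)
})

test_that("the acceptability checklist rejects with named reasons", {
  st <- llna_study("X", c(0.5, 1, 2), c(1, 3, 6))
  expect_true(checklist_screen(st)$accepted)
  st <- llna_study("X", c(0.5, 1, 2), c(1, 3, 6), flags = c(no_sls = FALSE))
  scr <- checklist_screen(st)
  expect_false(scr$accepted)
  expect_identical(scr$reasons, "no_sls")
  st <- llna_study("X", c(0.5, 1, 2), c(1, 3, 6), flags = c(no_sls = NA))
  expect_false(checklist_screen(st)$accepted)
  expect_error(llna_study("X", c(1, 2), c(1, 2), flags = c(bogus = TRUE)),
               "unknown checklist flags")
})

test_that("Approach 1 selects the most potent preferred-vehicle study", {
  mk <- function(ec3, vehicle) {
    st <- llna_study("X", c(ec3 / 2, ec3, ec3 * 2), c(2, 3, 5),
                     vehicle = vehicle)
    list(study = st, est = ec3_from_study(st))
  }
  cases <- list(mk(0.20, "AOO"), mk(0.25, "acetone"), mk(0.9, "AOO"),
                mk(0.05, "DMSO"))  # most potent overall, but wrong vehicle
  studies <- lapply(cases, `[[`, "study")
  ests <- lapply(cases, `[[`, "est")

  ref <- approach1_select(studies, ests)
  expect_identical(ref$approach, "A1")
  expect_equal(ref$n_studies, 2L)              # 0.20 and 0.25 tie as a pair
  expect_equal(ref$ci_low, 0.20)
  expect_equal(ref$ci_high, 0.25)
  expect_equal(ref$mean, 0.225)
  expect_identical(ref$ghs_class, "1A")

  single <- approach1_select(studies[3], ests[3])
  expect_equal(single$mean, 0.9)
  expect_equal(single$n_studies, 1L)
  expect_true(is.na(single$ci_low))

  expect_error(approach1_select(studies[4], ests[4]), "no accepted study")
})

test_that("Approach 2 aggregates with a censored t interval", {
  one <- approach2_aggregate(0.5)
  expect_equal(one$mean, 0.5)
  expect_true(is.na(one$ci_low))

  ref <- approach2_aggregate(c(1, 2, 3))
  expect_equal(ref$mean, 2)
  expect_identical(ref$ci_low, 0)  # raw bound -0.484 censored to zero
  expect_equal(ref$ci_high, 2 + qt(0.975, 2) * 1 / sqrt(3), tolerance = 1e-9)
  expect_identical(ref$ghs_class, "1A")

  # censoring holds for any input with a negative raw bound
  set.seed(7)
  for (i in 1:20) {
    v <- runif(sample(2:8, 1L), 0.01, 3)
    r <- approach2_aggregate(v)
    expect_gte(r$ci_low, 0)
    expect_lte(r$ci_low, r$mean)
    expect_gte(r$ci_high, r$mean)
  }

  norm <- approach2_aggregate(c(1, 2, 3), quantile = "normal")
  expect_lt(norm$ci_high, ref$ci_high)  # z narrower than t
  expect_error(approach2_aggregate(numeric(0)), "no accepted EC3")
})

test_that("CI width shrinks like 1/sqrt(n)", {
  set.seed(33)
  width <- function(n) {
    mean(replicate(400, {
      r <- approach2_aggregate(rnorm(n, 5, 0.5))
      r$ci_high - r$ci_low
    }))
  }
  # same sd, 4x the studies: expected width ratio ~ 2 (t quantiles near equal)
  expect_equal(width(8) / width(32), 2, tolerance = 0.2)
})

test_that("GHS classification is a total monotone step function", {
  expect_identical(ghs_classify(1.54), "1A")
  expect_identical(ghs_classify(10.57), "1B")
  expect_identical(ghs_classify(2.0), "1A")  # boundary belongs to 1A
  expect_identical(ghs_classify(NA), "NC")
  expect_error(ghs_classify(0), "positive")
  expect_error(ghs_classify(-1), "positive")
  x <- sort(10^runif(30, -3, 1.5))
  cls <- ghs_classify(x)
  expect_true(all(diff(match(cls, c("1A", "1B"))) >= 0))
})
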