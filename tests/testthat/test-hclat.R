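test_that("CV75 is the log-interpolated 75% viability crossing", {
  v <- dose_response(c(1, 2, 4), c(100, 75, 50), "ug/mL",
                     "viability_percent")
  expect_identical(hclat_cv75(v), 2)
  v <- dose_response(c(10, 20), c(100, 50), "ug/mL", "viability_percent")
  expect_equal(hclat_cv75(v), 10^mean(log10(c(10, 20))))
  v <- dose_response(c(10, 20, 40), c(95, 90, 82), "ug/mL",
                     "viability_percent")
  expect_identical(hclat_cv75(v), NA_real_)  # non-cytotoxic
})

test_that("the main-assay dose series starts at 1.2 x CV75, capped", {
  expect_equal(signif(hclat_dose_series(13.1, "DMSO")[1L], 3), 15.7)
  expect_equal(signif(hclat_dose_series(21.4, "PBS")[1L], 3), 25.7)
  expect_identical(hclat_dose_series(10000, "PBS")[1L], 5000)
  expect_identical(hclat_dose_series(NA, "DMSO")[1L], 1000)
  expect_error(hclat_dose_series(-1, "PBS"), "positive")

  d <- hclat_dose_series(13.1, "DMSO")
  expect_length(d, 8L)
  expect_true(all(diff(d) < 0))
  expect_equal(d[-8L] / d[-1L], rep(1.2, 7), tolerance = 1e-9)
})

test_that("substances below both RFI thresholds are negative", {
  conc <- hclat_dose_series(10, "PBS")
  conc <- sort(conc)
  runs <- list(make_hclat_run(conc, cd86 = rep(140, 8), cd54 = rep(180, 8)),
               make_hclat_run(conc, cd86 = rep(140, 8), cd54 = rep(180, 8)))
  r <- hclat_evaluate(runs)
  expect_false(r$positive)
  expect_true(is.na(r$mit))
})

test_that("a CD86 crossing in two runs yields a positive call and the MIT", {
  conc <- c(0.5, 0.7, 1.0, 1.4, 2.0)
  cd86 <- c(100, 120, 160, 190, 220)  # crosses 150 between 0.7 and 1.0
  runs <- list(make_hclat_run(conc, cd86), make_hclat_run(conc, cd86))
  r <- hclat_evaluate(runs)
  expect_true(r$positive)
  expect_true(r$cd86_positive)
  expect_false(r$cd54_positive)
  want <- 10^(log10(0.7) + (150 - 120) / (160 - 120) *
                (log10(1.0) - log10(0.7)))
  expect_equal(r$mit, want)
  expect_identical(r$mit, r$ec150)
  expect_true(is.na(r$ec200))
})

test_that("the MIT is the lower of EC150 and EC200", {
  conc <- c(0.5, 1, 2, 4, 8)
  cd86 <- c(100, 120, 140, 160, 200)  # crosses 150 between 2 and 4
  cd54 <- c(100, 150, 250, 300, 320)  # crosses 200 between 1 and 2
  runs <- list(make_hclat_run(conc, cd86, cd54),
               make_hclat_run(conc, cd86, cd54))
  r <- hclat_evaluate(runs)
  expect_true(r$cd86_positive && r$cd54_positive)
  expect_equal(r$mit, r$ec200)
  expect_lt(r$ec200, r$ec150)
})

test_that("concentrations with viability below 50% are disqualified", {
  conc <- c(0.5, 1, 2, 4)
  cd86 <- c(100, 120, 130, 200)          # only crosses 150 at the top dose
  viab <- c(100, 90, 80, 40)             # which is cytotoxic
  runs <- list(make_hclat_run(conc, cd86, viab = viab),
               make_hclat_run(conc, cd86, viab = viab))
  r <- hclat_evaluate(runs)
  expect_false(r$positive)
  expect_true(is.na(r$mit))
})

test_that("positivity requires the condition in two independent runs", {
  conc <- c(0.5, 1, 2, 4)
  hot <- c(100, 130, 160, 200)
  cold <- c(100, 110, 120, 130)
  r <- hclat_evaluate(list(make_hclat_run(conc, hot),
                           make_hclat_run(conc, cold)))
  expect_false(r$positive)
  r2 <- hclat_evaluate(list(make_hclat_run(conc, hot),
                            make_hclat_run(conc, cold),
                            make_hclat_run(conc, hot)))
  expect_true(r2$positive)
  expect_error(hclat_evaluate(list(make_hclat_run(conc, hot))),
               "two independent runs")
})

test_that("induction already at the lowest dose flags an undefined MIT", {
  conc <- c(0.5, 1, 2, 4)
  cd86 <- c(200, 220, 250, 280)
  r <- hclat_evaluate(list(make_hclat_run(conc, cd86),
                           make_hclat_run(conc, cd86)))
  expect_true(r$positive)
  expect_true(r$positive_at_lowest)
  expect_true(is.na(r$mit))
})
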