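test_that("the training-table generator is a pure function of spec and seed", {
  spec <- synthetic_spec(n_chemicals = 30, seed = 9)
  t1 <- generate_training_table(spec)
  t2 <- generate_training_table(spec)
  expect_identical(t1, t2)
  t3 <- generate_training_table(synthetic_spec(n_chemicals = 30, seed = 10))
  expect_false(identical(t1$ec3, t3$ec3))
  expect_equal(nrow(t1), 30L)
  expect_equal(sum(t1$split == "train"), 22L)  # 75% of 30, rounded
  expect_true(all(t1$ec3 > 0 & t1$mit > 0 & t1$imax >= 1))
  expect_true(all(t1$avg_lys_cys > 0 & t1$avg_lys_cys <= 100))
})

test_that("noiseless endpoint links are deterministic in EC3", {
  spec <- synthetic_spec(n_chemicals = 10, seed = 5,
                         noise_sd_log = list(depletion = 0, mit = 0,
                                             imax = 0, ec3 = 0))
  tab <- generate_training_table(spec)
  # equal true EC3 implies equal endpoint vectors: check via the pure links
  x <- tab$log10_ec3_true
  expect_equal(tab$mit, sensda:::.link_mit(x, spec$link))
  expect_equal(tab$avg_lys_cys,
               pmin(100, pmax(0.5, sensda:::.link_depletion(x, spec$link))))
  expect_equal(tab$ec3, 10^x)
})

test_that("the endpoint-potency links are strongly monotone", {
  tab <- generate_training_table(synthetic_spec(n_chemicals = 80, seed = 1))
  expect_gt(cor(tab$mit, tab$ec3, method = "spearman"), 0.9)
  expect_lt(cor(tab$avg_lys_cys, log10(tab$ec3), method = "spearman"), -0.5)
  expect_lt(cor(tab$imax, log10(tab$ec3), method = "spearman"), -0.5)
})

test_that("simulated LLNA studies cross SI = 3 at their own EC3", {
  noiseless <- synthetic_spec(llna = list(grid_mult = c(0.25, 0.5, 1, 2, 4),
                                          hill = 1.5, cv_log = 0,
                                          si_noise_log = 0))
  st <- simulate_llna_study(0.8, noiseless, study_seed = 2)
  expect_s3_class(st, "llna_study")
  expect_equal(ec3_from_study(st)$value, 0.8)  # EC3 on the grid: exact

  # EC3 between grid points: interpolated within the bracketing interval
  offgrid <- synthetic_spec(llna = list(grid_mult = c(0.3, 0.6, 1.5, 3),
                                        hill = 1.5, cv_log = 0,
                                        si_noise_log = 0))
  st <- simulate_llna_study(1, offgrid, study_seed = 2)
  est <- ec3_from_study(st)
  expect_identical(est$method, "interpolated")
  expect_gt(est$value, 0.6)
  expect_lt(est$value, 1.5)

  # corrupted checklist flags propagate to the screen
  st <- simulate_llna_study(0.8, noiseless, study_seed = 2,
                            failed_flags = "in_vivo_radiolabel")
  expect_identical(checklist_screen(st)$reasons, "in_vivo_radiolabel")
  expect_error(simulate_llna_study(-1, noiseless), "true_ec3 > 0")
})

test_that("assay fixtures round-trip through the endpoint calculators", {
  truth <- data.frame(chemical = c("A", "B"),
                      cys_depletion = c(55.2, 100),
                      lys_depletion = c(55.2, NA),
                      ks_ec15 = c(3.4, 9.5), ks_imax = c(3, 4),
                      cv75 = c(13.1, 24.6), mit = c(5, 11.6),
                      solvent = c("DMSO", "PBS"))
  fx <- generate_assay_fixtures(truth)
  ep <- assay_endpoints(fx$dpra, fx$keratinosens, fx$hclat)

  expect_equal(ep$avg_lys_cys[1L], 55.2, tolerance = 0.05 / 55.2)
  expect_identical(ep$dpra_model[2L], "cys_only")
  expect_true(ep$dpra_surrogate[2L])
  expect_equal(ep$avg_lys_cys[2L], 100)  # cysteine surrogate for the DA

  expect_equal(ep$ec15[1L], 3.4, tolerance = 0.05)   # log-grid interpolation
  expect_true(all(ep$ks_positive))

  # CV75 recovery within the 1.2-fold grid error
  run1 <- fx$hclat[fx$hclat$chemical == "A" & fx$hclat$run == 1, ]
  cv <- hclat_cv75(dose_response(run1$conc_ug_ml, run1$viability_pct,
                                 "ug/mL", "viability_percent"))
  expect_gte(cv, 12.4); expect_lte(cv, 13.8)

  expect_equal(ep$mit[1L], 5, tolerance = 0.02)
  expect_equal(ep$mit[2L], 11.6, tolerance = 0.03)
  expect_true(all(ep$hclat_positive))
})

test_that("a target MIT outside the dose series is flagged infeasible", {
  truth <- data.frame(chemical = "Z", cys_depletion = 50, lys_depletion = 50,
                      ks_ec15 = 3, ks_imax = 3,
                      cv75 = 100, mit = 1,  # lowest dose = 120/1.2^7 > 1
                      solvent = "PBS")
  fx <- generate_assay_fixtures(truth)
  expect_match(fx$flags, "infeasible_mit")
  ep <- assay_endpoints(fx$dpra, fx$keratinosens, fx$hclat)
  expect_true(is.na(ep$mit[1L]))
  expect_true(ep$hclat_positive[1L])  # positive at the lowest dose
})
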