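# small shared table so the ensemble tests stay fast
.tab <- generate_training_table(synthetic_spec(n_chemicals = 24, seed = 77))

test_that("the ensemble fit is reproducible and permutation-stable", {
  f1 <- ann_da(.tab, "D_hC", n_runs = 6, iterations = 300, seed = 3)
  f2 <- ann_da(.tab, "D_hC", n_runs = 6, iterations = 300, seed = 3)
  nd <- data.frame(avg_lys_cys = 50, mit = 5)
  expect_identical(predict(f1, nd), predict(f2, nd))

  p <- predict(f1, nd)
  per_run <- attr(p, "per_run")
  expect_equal(mean(sample(per_run)), p$mean_ec3, tolerance = 1e-9)
  expect_true(all(per_run > 0))
  expect_lte(p$ci_low, p$mean_ec3)
  expect_gte(p$ci_high, p$mean_ec3)

  f3 <- ann_da(.tab, "D_hC", n_runs = 6, iterations = 300, seed = 4)
  expect_false(identical(predict(f3, nd)$mean_ec3, p$mean_ec3))
})

test_that("ensemble_predict returns the per-run distribution", {
  ep <- ensemble_predict(.tab, c(avg_lys_cys = 50, mit = 5), "D_hC",
                         n_runs = 8, iterations = 300, seed = 1)
  expect_s3_class(ep, "ensemble_prediction")
  expect_length(ep$per_run_ec3, 8L)
  expect_equal(ep$mean_ec3, mean(ep$per_run_ec3))
  expect_lte(ep$ci_low, ep$mean_ec3)
  expect_gte(ep$ci_high, ep$mean_ec3)
  expect_gt(ep$ci_low, 0)
})

test_that("variant selection drives the required inputs", {
  expect_identical(ann_inputs("D_hC"), c("avg_lys_cys", "mit"))
  expect_identical(ann_inputs("D_hC_KS"), c("avg_lys_cys", "mit", "imax"))
  fit <- ann_da(.tab, "D_hC_KS", n_runs = 3, iterations = 100, seed = 1)
  expect_error(predict(fit, data.frame(avg_lys_cys = 50, mit = 5)),
               "imax")
  no_imax <- .tab[setdiff(names(.tab), "imax")]
  expect_error(ann_da(no_imax, "D_hC_KS", n_runs = 3, iterations = 50),
               "imax")
})

test_that("benchmark metrics match their closed forms", {
  fit <- ann_da(.tab, "D_hC", n_runs = 4, iterations = 1500, seed = 2)
  b <- ann_benchmark(fit, split = "train")
  pred <- predict(fit, .tab[.tab$split == "train", ])$mean_ec3
  obs <- .tab$ec3[.tab$split == "train"]
  lp <- log10(pred); lo <- log10(obs)
  expect_equal(b$rmse_log10, sqrt(mean((lo - lp)^2)))
  expect_equal(b$r_squared, 1 - sum((lo - lp)^2) / sum((lo - mean(lo))^2))
  expect_equal(b$n, sum(.tab$split == "train"))

  # hand-computed three-point example through the same formulas
  hand <- data.frame(obs = c(0.1, 1, 10), pred = c(0.2, 1, 5))
  lo <- log10(hand$obs); lp <- log10(hand$pred)
  r2 <- 1 - sum((lo - lp)^2) / sum((lo - mean(lo))^2)
  expect_equal(r2, 1 - (2 * log10(2)^2) / 2)  # closed form
  # perfect and mean-constant predictors bound the metric
  expect_equal(1 - 0 / sum((lo - mean(lo))^2), 1)
})

test_that("model methods expose the usual fitted-model surface", {
  fit <- ann_da(.tab, "D_hC", n_runs = 3, iterations = 300, seed = 6)
  expect_output(print(fit), "ensemble of 3 networks")
  expect_output(print(summary(fit)), "R2")
  expect_length(coef(fit), 3L)
  expect_length(coef(fit, run = 1L), 3L)  # three weight layers
  expect_length(fitted(fit), length(fit$train_rows))
  expect_length(residuals(fit), length(fit$train_rows))
  expect_equal(residuals(fit),
               log10(.tab$ec3[fit$train_rows]) - log10(fitted(fit)))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("an independent nonlinear learner agrees the table is learnable", {
  # cross-check of the synthetic link, not of the backprop implementation:
  # nnet's BFGS-trained single-hidden-layer net on the same log10 features
  # should also explain most of the variance
  tr <- .tab[.tab$split == "train", ]
  te <- .tab[.tab$split == "test", ]
  set.seed(1)
  fit <- nnet::nnet(x = log10(as.matrix(tr[c("avg_lys_cys", "mit")])),
                    y = log10(tr$ec3), size = 5, linout = TRUE,
                    maxit = 500, trace = FALSE)
  pred <- as.numeric(stats::predict(
    fit, log10(as.matrix(te[c("avg_lys_cys", "mit")]))))
  r2 <- 1 - sum((log10(te$ec3) - pred)^2) /
    sum((log10(te$ec3) - mean(log10(te$ec3)))^2)
  expect_gt(r2, 0.5)
})
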