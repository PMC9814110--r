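test_that("log min-max scaling is exact and invertible", {
  set.seed(21)
  x <- matrix(10^runif(40, -2, 2), ncol = 2)
  sc <- sensda:::make_scaler(x, 0.05)
  xs <- scale_inputs(x, sc)
  # training extremes map onto the margins
  expect_equal(min(xs[, 1L]), 0.05)
  expect_equal(max(xs[, 1L]), 0.95)
  # exact round trip
  expect_equal(unscale_outputs(xs, sc), x, tolerance = 1e-12)
  # out-of-range values extrapolate linearly and still invert
  xnew <- matrix(c(1e-3, 1e3), ncol = 2)
  expect_equal(unscale_outputs(scale_inputs(xnew, sc), sc), xnew,
               tolerance = 1e-12)
  expect_error(scale_inputs(matrix(c(-1, 1), ncol = 2), sc), "positive")
})

test_that("the forward pass matches a hand computation", {
  # all-zero weights: every logistic sees 0, output is 0.5
  zero <- list(list(W = matrix(0, 2, 5), b = rep(0, 5)),
               list(W = matrix(0, 5, 2), b = rep(0, 2)),
               list(W = matrix(0, 2, 1), b = 0))
  expect_equal(as.numeric(ann_forward(zero, matrix(c(0.3, 0.7), 1))), 0.5)

  # small non-trivial net, recomputed with explicit arithmetic
  set.seed(22)
  w <- sensda:::.ann_init(2L, c(5L, 2L), 0.5)
  x <- matrix(c(0.2, 0.8), 1)
  h1 <- logistic(x %*% w[[1L]]$W + matrix(w[[1L]]$b, 1))
  h2 <- logistic(h1 %*% w[[2L]]$W + matrix(w[[2L]]$b, 1))
  o <- logistic(h2 %*% w[[3L]]$W + matrix(w[[3L]]$b, 1))
  expect_equal(as.numeric(ann_forward(w, x)), as.numeric(o),
               tolerance = 1e-12)

  # logistic output is strictly inside (0, 1) for any finite weights
  set.seed(23)
  for (i in 1:10) {
    w <- sensda:::.ann_init(2L, c(5L, 2L), 10)
    out <- ann_forward(w, matrix(runif(10), ncol = 2))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(24)
  X <- matrix(runif(12, 0.1, 0.9), ncol = 3)
  y <- matrix(runif(4, 0.1, 0.9))
  w <- sensda:::.ann_init(3L, c(5L, 2L), 0.5)
  g <- sensda:::.ann_gradient(w, X, y)
  eps <- 1e-6
  analytic <- numeric(0)
  numeric_fd <- numeric(0)
  for (l in seq_along(w)) {
    for (slot in c("W", "b")) {
      for (i in seq_along(w[[l]][[slot]])) {
        wp <- w; wp[[l]][[slot]][i] <- wp[[l]][[slot]][i] + eps
        wm <- w; wm[[l]][[slot]][i] <- wm[[l]][[slot]][i] - eps
        fd <- (net_loss_oracle(wp, X, y) - net_loss_oracle(wm, X, y)) /
          (2 * eps)
        analytic <- c(analytic, g[[l]][[slot]][i])
        numeric_fd <- c(numeric_fd, fd)
      }
    }
  }
  expect_equal(analytic, numeric_fd, tolerance = 1e-6)
})

test_that("training is deterministic given the seed and fits a smooth map", {
  set.seed(25)
  x <- 10^runif(24, -1, 1)
  tab <- data.frame(avg_lys_cys = 100 / (1 + x), mit = 5 * x,
                    ec3 = x)  # noiseless monotone target
  cfg <- ann_config("D_hC", iterations = 2000)
  n1 <- train_ann(tab, cfg, seed = 4)
  n2 <- train_ann(tab, cfg, seed = 4)
  expect_identical(n1$weights, n2$weights)
  n3 <- train_ann(tab, cfg, seed = 5)
  expect_false(identical(n1$weights, n3$weights))

  # converged: scaled-space RMSE below 0.05
  Xs <- scale_inputs(as.matrix(tab[c("avg_lys_cys", "mit")]), n1$scaler_x)
  ys <- scale_inputs(as.matrix(tab$ec3), n1$scaler_y)
  expect_lt(sqrt(mean((ann_forward(n1, Xs) - ys)^2)), 0.05)

  # predictions are positive and reproduce the training targets closely
  pred <- predict_ec3(n1, tab)
  expect_true(all(pred > 0))
  expect_true(all(pred / tab$ec3 < 2 & pred / tab$ec3 > 0.5))
})

test_that("degenerate targets warn but still return a model", {
  tab <- data.frame(avg_lys_cys = c(10, 20, 30), mit = c(1, 2, 3),
                    ec3 = c(1, 1, 1))
  expect_warning(net <- train_ann(tab, ann_config(iterations = 10)),
                 "zero variance")
  expect_s3_class(net, "ann_net")
  expect_error(train_ann(tab[0, ], ann_config(iterations = 10)),
               "at least 2 rows")
  expect_error(train_ann(tab[, -1], ann_config(iterations = 10)),
               "missing columns")
})
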