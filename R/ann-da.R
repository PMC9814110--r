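#' Fit a neural-network defined approach as a random-initialization ensemble
#'
#' The central fitting function of the package. A defined approach (DA)
#' integrates the quantitative endpoints of the nonanimal skin-sensitization
#' assays -- DPRA Avg.Lys.Cys percent depletion, the h-CLAT minimum induction
#' threshold (MIT, ug/mL), and for the `"D_hC_KS"` variant the KeratinoSens
#' Imax fold induction -- into a prediction of the murine LLNA EC3 (percent),
#' the point of departure for quantitative risk assessment. The underlying
#' model is a fixed-topology feed-forward network (inputs -> 5 -> 2 -> 1,
#' logistic activations) trained by full-batch backpropagation with momentum
#' on log10-scaled inputs and target.
#'
#' Because the loss surface is non-convex, the network is trained `n_runs`
#' times (100 by default) from independent random initializations; the
#' ensemble's prediction for a chemical is the arithmetic mean of the per-run
#' EC3 values and its 95% confidence interval is the 2.5th/97.5th percentile
#' of the run distribution, a direct quantification of the uncertainty
#' contributed by the learning algorithm.
#'
#' @param data Training table: data frame with columns `avg_lys_cys`, `mit`,
#'   (`imax` for `"D_hC_KS"`), `ec3`, and optionally `split`
#'   (`"train"`/`"test"`) and `chemical`. Only `split == "train"` rows are
#'   fitted when a split column is present.
#' @param variant `"D_hC"` (DPRA + h-CLAT) or `"D_hC_KS"` (DPRA + h-CLAT +
#'   KeratinoSens).
#' @param n_runs Ensemble size (default 100).
#' @param seed Master seed; per-run initialization seeds are drawn from it,
#'   so the fit is fully reproducible.
#' @param config An [ann_config()]; its `variant` is overridden by `variant`.
#' @param ... Passed to [ann_config()] when `config` is not supplied.
#' @return An object of class `"ann_da"`: list with `runs` (the fitted
#'   `"ann_net"`s), `variant`, `config`, `data`, `train_rows`, `seed`,
#'   `run_seeds`.
#' @seealso [predict.ann_da()], [ensemble_predict()], [ann_benchmark()]
#' @examples
#' tab <- generate_training_table(synthetic_spec(n_chemicals = 20, seed = 1))
#' fit <- ann_da(tab, variant = "D_hC", n_runs = 5, iterations = 200, seed = 1)
#' predict(fit, data.frame(avg_lys_cys = 50, mit = 5))
#' @export
ann_da <- function(data, variant = c("D_hC", "D_hC_KS"), n_runs = 100L,
                   seed = 1L, config = NULL, ...) {
  variant <- match.arg(variant)
  if (is.null(config)) config <- ann_config(variant = variant, ...)
  config$variant <- variant
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("an ensemble needs at least 2 runs", call. = FALSE)

  train_rows <- if ("split" %in% names(data))
    which(data$split == "train") else seq_len(nrow(data))
  train <- data[train_rows, , drop = FALSE]
  if ("chemical" %in% names(train) && anyDuplicated(train$chemical))
    stop("duplicate chemical keys within the training split", call. = FALSE)

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  runs <- lapply(run_seeds, function(s) train_ann(train, config, seed = s))

  structure(list(runs = runs, variant = variant, config = config,
                 data = data, train_rows = train_rows,
                 seed = seed, run_seeds = run_seeds),
            class = "ann_da")
}

#' Predict LLNA EC3 from a fitted defined-approach ensemble
#'
#' @param object An [ann_da] fit.
#' @param newdata Data frame of endpoint vectors (columns per
#'   [ann_inputs()]); defaults to the training rows.
#' @param level Confidence level for the percentile interval (default 0.95).
#' @param ... Unused.
#' @return Data frame with one row per input: `mean_ec3`, `ci_low`,
#'   `ci_high` (percent). The per-run prediction matrix (rows = inputs,
#'   columns = runs) is attached as attribute `"per_run"`.
#' @export
predict.ann_da <- function(object, newdata = NULL, level = 0.95, ...) {
  if (is.null(newdata))
    newdata <- object$data[object$train_rows, , drop = FALSE]
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  per_run <- vapply(object$runs, function(net) predict_ec3(net, newdata),
                    numeric(nrow(newdata)))
  per_run <- matrix(per_run, nrow = nrow(newdata))
  a <- (1 - level) / 2
  qs <- t(apply(per_run, 1L, stats::quantile, probs = c(a, 1 - a),
                names = FALSE, type = 7))
  out <- data.frame(mean_ec3 = rowMeans(per_run),
                    ci_low = pmax(0, qs[, 1L]), ci_high = qs[, 2L])
  if ("chemical" %in% names(newdata)) out <- cbind(chemical = newdata$chemical, out)
  attr(out, "per_run") <- per_run
  out
}

#' Ensemble EC3 prediction for a single endpoint vector
#'
#' Convenience wrapper: trains an `n_runs` ensemble on `data` and predicts
#' the EC3 for one chemical's endpoint vector, returning the full per-run
#' distribution.
#'
#' @param data Training table (see [ann_da()]).
#' @param endpoints Named list/vector or one-row data frame of endpoint
#'   values.
#' @param variant,n_runs,seed,config,... As in [ann_da()].
#' @return An object of class `"ensemble_prediction"`: list with
#'   `per_run_ec3` (length `n_runs`), `mean_ec3`, `ci_low`, `ci_high`.
#' @export
ensemble_predict <- function(data, endpoints, variant = c("D_hC", "D_hC_KS"),
                             n_runs = 100L, seed = 1L, config = NULL, ...) {
  fit <- ann_da(data, variant = variant, n_runs = n_runs, seed = seed,
                config = config, ...)
  pred <- predict(fit, as.data.frame(as.list(endpoints)))
  per_run <- as.numeric(attr(pred, "per_run")[1L, ])
  structure(list(per_run_ec3 = per_run, mean_ec3 = pred$mean_ec3[1L],
                 ci_low = pred$ci_low[1L], ci_high = pred$ci_high[1L],
                 n_runs = length(per_run), variant = fit$variant),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("Ensemble EC3 prediction [%s, %d runs]: %.4g%% (95%% CI %.4g-%.4g)\n",
              x$variant, x$n_runs, x$mean_ec3, x$ci_low, x$ci_high))
  invisible(x)
}

#' Benchmark ensemble predictions against observed EC3 values
#'
#' Computes the coefficient of determination and root-mean-squared error
#' between predicted and observed EC3 in log10 space, the conventional scale
#' for benchmarking potency models spanning several orders of magnitude.
#'
#' @param object An [ann_da] fit.
#' @param data Table with endpoint columns and `ec3`; defaults to the fit's
#'   own table.
#' @param split `"train"`, `"test"` or `"all"` rows of `data` (requires a
#'   `split` column for the first two).
#' @return List with `r_squared`, `rmse_log10`, `n`.
#' @export
ann_benchmark <- function(object, data = NULL,
                          split = c("test", "train", "all")) {
  split <- match.arg(split)
  stopifnot(inherits(object, "ann_da"))
  if (is.null(data)) data <- object$data
  if (split != "all") {
    if (!"split" %in% names(data))
      stop("data has no split column", call. = FALSE)
    data <- data[data$split == split, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("empty evaluation split", call. = FALSE)
  pred <- predict(object, data)$mean_ec3
  obs <- data$ec3
  lp <- log10(pred); lo <- log10(obs)
  ss_res <- sum((lo - lp)^2)
  ss_tot <- sum((lo - mean(lo))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse_log10 = sqrt(mean((lo - lp)^2)),
       n = nrow(data))
}

#' @export
print.ann_da <- function(x, ...) {
  cat(sprintf("Defined approach ANN %s: ensemble of %d networks (%d-5-2-1, logistic)\n",
              x$variant, length(x$runs), length(ann_inputs(x$variant))))
  cat(sprintf("  trained on %d chemicals, %d epochs/run, master seed %d\n",
              length(x$train_rows), x$config$iterations, x$seed))
  invisible(x)
}

#' @export
summary.ann_da <- function(object, ...) {
  train <- ann_benchmark(object, split = if ("split" %in% names(object$data))
    "train" else "all")
  test <- if ("split" %in% names(object$data) &&
              any(object$data$split == "test"))
    ann_benchmark(object, split = "test") else NULL
  out <- list(fit = object, train = train, test = test)
  class(out) <- "summary.ann_da"
  out
}

#' @export
print.summary.ann_da <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  train: R2 = %.3f, RMSE(log10 EC3) = %.3f (n = %d)\n",
              x$train$r_squared, x$train$rmse_log10, x$train$n))
  if (!is.null(x$test))
    cat(sprintf("  test:  R2 = %.3f, RMSE(log10 EC3) = %.3f (n = %d)\n",
                x$test$r_squared, x$test$rmse_log10, x$test$n))
  invisible(x)
}

#' @export
coef.ann_da <- function(object, run = NULL, ...) {
  if (is.null(run)) lapply(object$runs, `[[`, "weights")
  else object$runs[[run]]$weights
}

#' @export
fitted.ann_da <- function(object, ...) {
  predict(object)$mean_ec3
}

#' @export
residuals.ann_da <- function(object, ...) {
  train <- object$data[object$train_rows, , drop = FALSE]
  log10(train$ec3) - log10(fitted(object))
}

#' Observed-versus-predicted plot for a fitted defined approach
#'
#' @param x An [ann_da] fit.
#' @param newdata Table to plot (defaults to the fit's full table).
#' @param ... Passed to [plot()].
#' @export
plot.ann_da <- function(x, newdata = NULL, ...) {
  data <- if (is.null(newdata)) x$data else newdata
  pred <- predict(x, data)
  graphics::plot(data$ec3, pred$mean_ec3, log = "xy",
                 xlab = "observed LLNA EC3 (%)",
                 ylab = "predicted EC3 (%)",
                 main = sprintf("ANN %s ensemble", x$variant), ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2)
  invisible(pred)
}
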