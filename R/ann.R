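# Feed-forward network core for the defined approaches: fixed topology
# inputs -> 5 -> 2 -> 1, logistic activations on hidden and output layers,
# trained by full-batch backpropagation with a momentum term on half the
# summed squared error. Inputs and the EC3 target are log10-transformed and
# min-max scaled into [margin, 1 - margin] so the logistic output can
# represent every training target.

.logistic <- function(z) 1 / (1 + exp(-z))

#' Training configuration for a defined-approach network
#'
#' @param variant `"D_hC"` (inputs: DPRA Avg.Lys.Cys and h-CLAT MIT) or
#'   `"D_hC_KS"` (additionally KeratinoSens Imax).
#' @param iterations Number of full-batch training epochs (default 10000).
#' @param learning_rate Gradient step size (default 0.2).
#' @param momentum Momentum coefficient in `[0, 1)` (default 0.5).
#' @param init_range Weights and biases are initialized uniformly on
#'   `(-init_range, init_range)` (default 0.5).
#' @param scaling_margin Scaled values occupy `[margin, 1 - margin]`
#'   (default 0.05).
#' @return A list of class `"ann_config"`.
#' @export
ann_config <- function(variant = c("D_hC", "D_hC_KS"), iterations = 10000L,
                       learning_rate = 0.2, momentum = 0.5,
                       init_range = 0.5, scaling_margin = 0.05) {
  variant <- match.arg(variant)
  stopifnot(iterations >= 1L, learning_rate > 0,
            momentum >= 0, momentum < 1,
            init_range > 0, scaling_margin >= 0, scaling_margin < 0.5)
  structure(list(variant = variant,
                 hidden_sizes = c(5L, 2L),  # fixed topology
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate, momentum = momentum,
                 init_range = init_range, scaling_margin = scaling_margin),
            class = "ann_config")
}

#' Input variables required by a model variant
#' @param variant `"D_hC"` or `"D_hC_KS"`.
#' @return Character vector of column names.
#' @export
ann_inputs <- function(variant = c("D_hC", "D_hC_KS")) {
  variant <- match.arg(variant)
  if (variant == "D_hC") c("avg_lys_cys", "mit") else
    c("avg_lys_cys", "mit", "imax")
}

# per-column log10 min-max scaler frozen on the training set
make_scaler <- function(x, margin) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all values entering the log10 scaler must be positive and finite",
         call. = FALSE)
  lx <- log10(x)
  lo <- apply(lx, 2L, min)
  hi <- apply(lx, 2L, max)
  structure(list(log_min = lo, log_max = hi, margin = margin),
            class = "ann_scaler")
}

#' Scale raw endpoint/EC3 values for the network
#'
#' Values are log10-transformed and mapped linearly so the training-set
#' minimum lands at `margin` and the maximum at `1 - margin`. The inverse
#' transform is exact on the forward image.
#'
#' @param x Matrix/data frame (or vector for a single-column scaler) of
#'   positive values.
#' @param scaler A scaler as stored in a fitted network (`$scaler_x`,
#'   `$scaler_y`).
#' @return Matrix of scaled values.
#' @export
scale_inputs <- function(x, scaler) {
  stopifnot(inherits(scaler, "ann_scaler"))
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all values entering the log10 scaler must be positive and finite",
         call. = FALSE)
  lx <- log10(x)
  rng <- scaler$log_max - scaler$log_min
  rng[rng == 0] <- 1  # degenerate column: maps to the midpoint
  m <- scaler$margin
  sweep(sweep(lx, 2L, scaler$log_min), 2L, rng, "/") * (1 - 2 * m) + m
}

#' @rdname scale_inputs
#' @export
unscale_outputs <- function(x, scaler) {
  stopifnot(inherits(scaler, "ann_scaler"))
  x <- as.matrix(x)
  rng <- scaler$log_max - scaler$log_min
  rng[rng == 0] <- 1
  m <- scaler$margin
  lx <- sweep(sweep((x - m) / (1 - 2 * m), 2L, rng, "*"), 2L,
              scaler$log_min, "+")
  10^lx
}

.ann_init <- function(n_in, hidden, init_range) {
  sizes <- c(n_in, hidden, 1L)
  w <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    w[[l]] <- list(
      W = matrix(stats::runif(sizes[l] * sizes[l + 1L],
                              -init_range, init_range),
                 sizes[l], sizes[l + 1L]),
      b = stats::runif(sizes[l + 1L], -init_range, init_range))
  }
  w
}

# forward pass storing activations (for backprop)
.ann_forward_full <- function(weights, X) {
  acts <- list(X)
  a <- X
  for (l in seq_along(weights)) {
    a <- .logistic(sweep(a %*% weights[[l]]$W, 2L, weights[[l]]$b, "+"))
    acts[[l + 1L]] <- a
  }
  acts
}

#' Forward pass of a defined-approach network on scaled inputs
#'
#' @param net A fitted network from [train_ann()] (or a bare weight list).
#' @param x_scaled Matrix of scaled inputs (rows = cases).
#' @return Matrix of scaled outputs in `(0, 1)`.
#' @export
ann_forward <- function(net, x_scaled) {
  weights <- if (inherits(net, "ann_net")) net$weights else net
  x_scaled <- as.matrix(x_scaled)
  acts <- .ann_forward_full(weights, x_scaled)
  acts[[length(acts)]]
}

# gradient of E = 0.5 * sum((o - y)^2) wrt all weights/biases (classical
# batch backprop convention: per-pattern contributions are summed)
.ann_gradient <- function(weights, X, y) {
  acts <- .ann_forward_full(weights, X)
  L <- length(weights)
  out <- acts[[L + 1L]]
  delta <- (out - y) * out * (1 - out)
  grads <- vector("list", L)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      a <- acts[[l]]
      delta <- (delta %*% t(weights[[l]]$W)) * a * (1 - a)
    }
  }
  grads
}

.ann_loss <- function(weights, X, y) {
  out <- .ann_forward_full(weights, X)[[length(weights) + 1L]]
  0.5 * sum((out - y)^2)
}

#' Train a single defined-approach network
#'
#' Fits the fixed-topology network (inputs -> 5 -> 2 -> 1, logistic
#' activations throughout) by full-batch gradient descent with momentum on
#' half the summed squared error in scaled space, for exactly
#' `config$iterations` epochs. Scaling parameters are frozen from the
#' training table. Deterministic given `seed`.
#'
#' @param data Data frame with the variant's input columns (see
#'   [ann_inputs()]) and an `ec3` column (percent, positive).
#' @param config An [ann_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `"ann_net"`: weights, scalers, config, seed,
#'   and the final training loss.
#' @export
train_ann <- function(data, config = ann_config(), seed = 1L) {
  stopifnot(inherits(config, "ann_config"))
  vars <- ann_inputs(config$variant)
  miss <- setdiff(c(vars, "ec3"), names(data))
  if (length(miss))
    stop("training table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) < 2L)
    stop("training requires at least 2 rows", call. = FALSE)
  X <- as.matrix(data[vars])
  y <- as.matrix(data[["ec3"]])
  if (stats::var(log10(y)) == 0)
    warning("zero variance in the training target; the scaled target is constant")

  scaler_x <- make_scaler(X, config$scaling_margin)
  scaler_y <- make_scaler(y, config$scaling_margin)
  Xs <- scale_inputs(X, scaler_x)
  ys <- scale_inputs(y, scaler_y)

  set.seed(seed)
  weights <- .ann_init(ncol(Xs), config$hidden_sizes, config$init_range)
  vel <- lapply(weights, function(w)
    list(W = w$W * 0, b = w$b * 0))

  lr <- config$learning_rate
  mom <- config$momentum
  for (it in seq_len(config$iterations)) {
    g <- .ann_gradient(weights, Xs, ys)
    for (l in seq_along(weights)) {
      vel[[l]]$W <- mom * vel[[l]]$W - lr * g[[l]]$W
      vel[[l]]$b <- mom * vel[[l]]$b - lr * g[[l]]$b
      weights[[l]]$W <- weights[[l]]$W + vel[[l]]$W
      weights[[l]]$b <- weights[[l]]$b + vel[[l]]$b
    }
  }

  structure(list(weights = weights, scaler_x = scaler_x, scaler_y = scaler_y,
                 config = config, seed = seed,
                 final_loss = .ann_loss(weights, Xs, ys)),
            class = "ann_net")
}

#' Predict EC3 from a single trained network
#'
#' Applies the frozen log10 min-max scaling, the forward pass, and the exact
#' inverse transform; predictions are strictly positive percent
#' concentrations by construction.
#'
#' @param net An `"ann_net"` from [train_ann()].
#' @param endpoints Data frame (or named vector/list) with the variant's
#'   input columns.
#' @return Numeric vector of predicted EC3 (percent).
#' @export
predict_ec3 <- function(net, endpoints) {
  stopifnot(inherits(net, "ann_net"))
  vars <- ann_inputs(net$config$variant)
  if (!is.data.frame(endpoints)) endpoints <- as.data.frame(as.list(endpoints))
  miss <- setdiff(vars, names(endpoints))
  if (length(miss))
    stop("endpoint vector is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(endpoints[vars])
  out <- ann_forward(net, scale_inputs(X, net$scaler_x))
  as.numeric(unscale_outputs(out, net$scaler_y))
}

#' @export
print.ann_net <- function(x, ...) {
  cat(sprintf("Defined-approach network [%s]: %d-5-2-1, logistic; %d epochs (seed %d)\n",
              x$config$variant, length(ann_inputs(x$config$variant)),
              x$config$iterations, x$seed))
  cat(sprintf("  final training loss (scaled space): %.3g\n", x$final_loss))
  invisible(x)
}
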