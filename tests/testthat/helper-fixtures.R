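# Shared builders and independent oracles used across test files.

# brute-force dense-grid scan of the same piecewise-linear interpolant;
# independent of crossing_concentration's segment logic
crossing_oracle <- function(conc, resp, threshold, direction, scale,
                            n_grid = 1e5) {
  x <- if (scale == "log") log10(conc) else conc
  g <- seq(x[1L], x[length(x)], length.out = n_grid)
  r <- stats::approx(x, resp, xout = g)$y
  met <- if (direction == "up") r >= threshold else r <= threshold
  if (direction == "up" && resp[1L] > threshold) return(NA_real_)
  if (direction == "down" && resp[1L] < threshold) return(NA_real_)
  i <- which(met)[1L]
  if (is.na(i)) return(NA_real_)
  if (scale == "log") 10^g[i] else g[i]
}

make_ks_series <- function(conc, fold, viab = rep(100, length(conc))) {
  list(induction = dose_response(conc, fold, "uM", "fold_induction"),
       viability = dose_response(conc, viab, "uM", "viability_percent"))
}

# one h-CLAT run from response vectors on a shared grid
make_hclat_run <- function(conc, cd86, cd54 = rep(100, length(conc)),
                           viab = rep(100, length(conc))) {
  hclat_run(dose_response(conc, cd86, "ug/mL", "rfi_percent"),
            dose_response(conc, cd54, "ug/mL", "rfi_percent"),
            dose_response(conc, viab, "ug/mL", "viability_percent"))
}

make_si_series <- function(conc, si) {
  dose_response(conc, si, "pct", "stimulation_index")
}

logistic <- function(z) 1 / (1 + exp(-z))

# total loss used by the trainer, recomputed independently for finite
# differences: half the summed squared error of the forward pass
net_loss_oracle <- function(weights, X, y) {
  a <- X
  for (l in seq_along(weights))
    a <- logistic(sweep(a %*% weights[[l]]$W, 2L, weights[[l]]$b, "+"))
  0.5 * sum((a - y)^2)
}
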