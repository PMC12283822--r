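# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route (grid search, numerical integration,
# direct matrix algebra) so agreement is informative.

# Brute-force censored-Weibull MLE: 200x200 grid over (shape, scale) with
# two zoom rounds around the running argmax. Independent of the package's
# gradient-based optimizer.
grid_search_weibull <- function(time, status, shape_lim = c(0.2, 8),
                                scale_lim = NULL) {
  if (is.null(scale_lim)) scale_lim <- c(min(time) / 4, max(time) * 10)
  ll <- function(k, lam) {
    z <- (time / lam)^k
    sum(status * (log(k) - k * log(lam) + (k - 1) * log(time))) - sum(z)
  }
  best <- c(NA, NA)
  for (round in 1:3) {
    ks <- exp(seq(log(shape_lim[1]), log(shape_lim[2]), length.out = 200))
    ls <- exp(seq(log(scale_lim[1]), log(scale_lim[2]), length.out = 200))
    vals <- outer(ks, ls, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(ks[idx[1]], ls[idx[2]])
    # zoom: two grid cells around the argmax
    shape_lim <- c(ks[max(idx[1] - 2, 1)], ks[min(idx[1] + 2, 200)])
    scale_lim <- c(ls[max(idx[2] - 2, 1)], ls[min(idx[2] + 2, 200)])
  }
  c(shape = best[1], scale = best[2])
}

# Weibull moments by adaptive numerical integration of the density.
integrate_weibull_moments <- function(shape, scale) {
  f1 <- function(t) t * stats::dweibull(t, shape, scale)
  f2 <- function(t) t^2 * stats::dweibull(t, shape, scale)
  m1 <- stats::integrate(f1, 0, Inf, rel.tol = 1e-12)$value
  m2 <- stats::integrate(f2, 0, Inf, rel.tol = 1e-12)$value
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Step-function lookup of a KM curve at arbitrary times.
km_value <- function(curve, t) {
  i <- findInterval(t, curve$time)
  curve$survival[pmax(i, 1)]
}

# Exhaustive isotonic (non-increasing) least-squares fit for short
# sequences: optimizes over all level-set partitions.
exhaustive_monotone_fit <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  # enumerate all 2^(n-1) partitions into contiguous pooled blocks
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    fit <- numeric(n)
    for (b in seq_along(starts)) {
      fit[starts[b]:ends[b]] <- mean(y[starts[b]:ends[b]])
    }
    if (all(diff(fit) <= 1e-12)) {
      sse <- sum((y - fit)^2)
      if (sse < best_sse - 1e-15) { best_sse <- sse; best <- fit }
    }
  }
  best
}

# Arm-level draw from the meta-regression model itself (correctly
# specified): known design, known variances, normal errors.
simulate_model_arms <- function(design, beta, tau) {
  b <- stats::rnorm(length(unique(design$trial_id)), 0, tau)
  names(b) <- unique(design$trial_id)
  mu <- beta[1] + beta[2] * design$treatment + beta[3] * design$log_mean
  design$log_sd <- mu + b[design$trial_id] +
    stats::rnorm(nrow(design), 0, sqrt(design$var_log_sd))
  design
}

# A small, quick deterministic portfolio for structural tests.
quick_portfolio <- function(seed = 1, n_trials = 4, ...) {
  simulate_portfolio(portfolio_truth(n_trials = n_trials, n_per_arm = 1500,
                                     seed = seed, ...))
}
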