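# Censored Weibull fitting per trial arm and the derived variability
# outcome: log(SD) of the event-time distribution with a delta-method
# sampling variance.
#
# Parameterization: survival S(t) = exp(-(t/lambda)^k) with shape k and
# scale lambda (months). The likelihood is maximized over
# (log k, log lambda) so the parameter space is unconstrained and the
# observed information refers to the log parameters.

# log-likelihood pieces; th = c(log_shape, log_scale)
wb_negll <- function(th, lt, status) {
  k <- exp(th[1])
  u <- lt - th[2]
  ku <- k * u
  if (any(ku > 690)) return(1e10) # exp overflow guard far outside optimum
  z <- exp(ku)
  -(sum(status * (th[1] - th[2] + (k - 1) * u)) - sum(z))
}

wb_negll_grad <- function(th, lt, status) {
  k <- exp(th[1])
  u <- lt - th[2]
  z <- exp(pmin(k * u, 690))
  g1 <- sum(status * (1 + k * u)) - k * sum(z * u)
  g2 <- k * (sum(z) - sum(status))
  -c(g1, g2)
}

# Analytic Hessian of the negative log-likelihood in (log k, log lambda).
wb_negll_hess <- function(th, lt, status) {
  k <- exp(th[1])
  u <- lt - th[2]
  z <- exp(pmin(k * u, 690))
  D <- sum(status)
  szu <- sum(z * u)
  sz <- sum(z)
  h11 <- k * sum(status * u) - k * szu - k^2 * sum(z * u^2)
  h12 <- -k * D + k * sz + k^2 * szu
  h22 <- -k^2 * sz
  -matrix(c(h11, h12, h12, h22), 2, 2)
}

# Starting values: shape from the slope of log(-log S_KM) against log t,
# scale from the Kaplan-Meier 63.2% quantile; fall back to
# (1, mean event time) when the regression is degenerate.
wb_init <- function(time, status) {
  fallback <- c(0, log(mean(time[status == 1])))
  init <- tryCatch({
    sf <- survival::survfit(survival::Surv(time, status) ~ 1)
    keep <- sf$n.event > 0 & sf$surv > 1e-8 & sf$surv < 1 - 1e-8
    tt <- sf$time[keep]
    ss <- sf$surv[keep]
    if (length(tt) < 2) stop("degenerate")
    y <- log(-log(ss))
    x <- log(tt)
    b <- stats::cov(x, y)
    k0 <- if (is.finite(b) && stats::var(x) > 0) stats::cov(x, y) / stats::var(x) else 1
    if (!is.finite(k0) || k0 <= 0.05) k0 <- 1
    # t where S = exp(-1)
    i <- which(ss <= exp(-1))[1]
    lam0 <- if (!is.na(i)) tt[i] else max(tt) * 1.5
    c(log(k0), log(lam0))
  }, error = function(e) fallback)
  if (any(!is.finite(init))) init <- fallback
  init
}

#' Fit a right-censored Weibull model to one trial arm
#'
#' Maximizes the censored Weibull log-likelihood over
#' \eqn{(\log k, \log \lambda)} using BFGS with analytic gradients followed
#' by damped Newton refinement until the gradient norm falls below
#' \code{1e-8}. The covariance of the log parameters is the inverse of the
#' observed information at the optimum.
#'
#' @param ipd Data frame with columns \code{time} (positive, months) and
#'   \code{status} (1 = event/death, 0 = censored).
#' @return An object of class \code{weibull_fit}: a list with elements
#'   \code{shape}, \code{scale}, \code{loglik}, \code{cov_log_params}
#'   (2x2, order \code{log_shape}, \code{log_scale}), \code{n},
#'   \code{n_events}, \code{gradient_norm}, \code{converged}.
#' @examples
#' ipd <- data.frame(time = c(1, 2, 3, 4, 5), status = 1)
#' fit <- fit_weibull(ipd)
#' weibull_moments(fit)
#' @export
fit_weibull <- function(ipd) {
  ipd <- assert_ipd(ipd)
  ev <- ipd$time[ipd$status == 1]
  if (length(ev) < 2)
    stop("insufficient events: need at least 2 events to fit a Weibull model",
         call. = FALSE)
  if (length(unique(ev)) < 2)
    stop("insufficient events: all events at a single time (shape diverges)",
         call. = FALSE)
  lt <- log(ipd$time)
  status <- as.numeric(ipd$status)

  th <- wb_init(ipd$time, status)
  opt <- stats::optim(th, wb_negll, wb_negll_grad, lt = lt, status = status,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  th <- opt$par
  # Newton polish with step halving
  f <- wb_negll(th, lt, status)
  gnorm <- NA_real_
  for (it in 1:100) {
    g <- wb_negll_grad(th, lt, status)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < 1e-8) break
    H <- wb_negll_hess(th, lt, status)
    step <- tryCatch(solve(H, g), error = function(e) g * 1e-3)
    alpha <- 1
    repeat {
      thn <- th - alpha * step
      fn <- wb_negll(thn, lt, status)
      if (is.finite(fn) && fn <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break
    th <- th - alpha * step
    f <- wb_negll(th, lt, status)
  }
  g <- wb_negll_grad(th, lt, status)
  gnorm <- sqrt(sum(g^2))
  shape <- exp(th[1])
  scale <- exp(th[2])
  if (!is.finite(shape) || shape > 1e4 || shape < 1e-4)
    stop(sprintf("weibull fit did not converge: shape estimate %.3g is degenerate",
                 shape), call. = FALSE)
  if (gnorm >= 1e-6)
    stop(sprintf(paste0("weibull fit did not converge: gradient norm %.3g ",
                        "(shape %.4g, scale %.4g, n = %d, events = %d)"),
                 gnorm, shape, scale, nrow(ipd), sum(status)), call. = FALSE)
  H <- wb_negll_hess(th, lt, status)
  cov <- tryCatch(solve(H), error = function(e)
    stop("singular observed information in weibull fit", call. = FALSE))
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(c("log_shape", "log_scale"), c("log_shape", "log_scale"))
  structure(list(
    shape = shape, scale = scale,
    loglik = -f,
    cov_log_params = cov,
    n = nrow(ipd), n_events = as.integer(sum(status)),
    gradient_norm = gnorm,
    converged = gnorm < 1e-8
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Censored Weibull fit\n")
  cat(sprintf("  shape k      = %.5g\n", x$shape))
  cat(sprintf("  scale lambda = %.5g months\n", x$scale))
  cat(sprintf("  n = %d, events = %d, loglik = %.4f\n", x$n, x$n_events, x$loglik))
  m <- weibull_moments(x)
  cat(sprintf("  mean = %.4g, sd = %.4g, log(SD) = %.4f (var %.3g)\n",
              m[["mean"]], m[["sd"]], log_sd(x), var_log_sd(x)))
  invisible(x)
}

wb_mean <- function(shape, scale) scale * gamma(1 + 1 / shape)

wb_sd <- function(shape, scale) {
  # log-scale evaluation keeps large shape/scale combinations stable
  v <- exp(lgamma(1 + 2 / shape) - 2 * lgamma(1 + 1 / shape)) - 1 # squared CV
  scale * gamma(1 + 1 / shape) * sqrt(pmax(v, 0))
}

#' Closed-form moments of the fitted event-time distribution
#'
#' Mean \eqn{\lambda\Gamma(1+1/k)} and standard deviation
#' \eqn{\lambda\sqrt{\Gamma(1+2/k)-\Gamma(1+1/k)^2}} of the (uncensored)
#' Weibull law. Censoring enters the fit through the likelihood only; the
#' moments describe the full extrapolated time-to-death distribution.
#'
#' @param fit A \code{weibull_fit}, or any list with elements \code{shape}
#'   and \code{scale}.
#' @return Named numeric vector \code{c(mean, sd)} in months.
#' @export
weibull_moments <- function(fit) {
  shape <- fit$shape
  scale <- fit$scale
  stopifnot(is.numeric(shape), is.numeric(scale), shape > 0, scale > 0)
  c(mean = wb_mean(shape, scale), sd = wb_sd(shape, scale))
}

#' Variability and location outcomes of a fitted arm
#'
#' \code{log_sd} and \code{log_mean} are the natural logarithms of the
#' Weibull standard deviation and mean of time to death; log(SD) is the
#' arm-level variability outcome carried into the meta-regression.
#'
#' @param fit A \code{weibull_fit}.
#' @return Scalar.
#' @export
log_sd <- function(fit) as.numeric(log(weibull_moments(fit)[["sd"]]))

#' @rdname log_sd
#' @export
log_mean <- function(fit) as.numeric(log(weibull_moments(fit)[["mean"]]))

# Gradient of log SD with respect to (log k, log lambda).
# d logSD / d log lambda = 1 exactly; the shape component uses digamma.
log_sd_grad <- function(shape) {
  A <- gamma(1 + 2 / shape)
  B <- gamma(1 + 1 / shape)
  V <- A - B^2
  dk <- -(1 / shape) * (A * digamma(1 + 2 / shape) - B^2 * digamma(1 + 1 / shape)) / V
  c(log_shape = dk, log_scale = 1)
}

#' Delta-method sampling variance of log(SD)
#'
#' First-order variance propagation of \code{log_sd} through the
#' covariance of the fitted log parameters:
#' \eqn{g^\top \Sigma g} with \eqn{g = (\partial \log SD/\partial \log k, 1)}.
#'
#' @param fit A \code{weibull_fit}.
#' @return Positive scalar.
#' @export
var_log_sd <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit") || is.list(fit))
  C <- fit$cov_log_params
  if (is.null(C)) stop("fit has no `cov_log_params`", call. = FALSE)
  g <- log_sd_grad(fit$shape)
  v <- as.numeric(t(g) %*% C %*% g)
  if (!is.finite(v) || v <= 0)
    stop("delta-method variance of log(SD) is not positive (singular information?)",
         call. = FALSE)
  v
}

#' Nonparametric bootstrap variance of log(SD)
#'
#' Case-resampling bootstrap used as an independent check on the
#' delta-method variance: refits the Weibull model to \code{B} resamples
#' and returns the empirical variance of log(SD).
#'
#' @param ipd Arm-level individual participant data.
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @return Positive scalar.
#' @export
bootstrap_var_log_sd <- function(ipd, B = 500, seed = 1) {
  ipd <- assert_ipd(ipd)
  stopifnot(B >= 100)
  n <- nrow(ipd)
  with_seed(seed, {
    vals <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(log_sd(fit_weibull(ipd[idx, , drop = FALSE])),
               error = function(e) NA_real_)
    }, numeric(1))
    fail <- sum(is.na(vals))
    if (fail > 0.1 * B)
      stop(sprintf("bootstrap refits failed in %d of %d resamples", fail, B),
           call. = FALSE)
    stats::var(vals[!is.na(vals)])
  })
}

#' Summarize one trial arm as a meta-regression observation
#'
#' Fits the censored Weibull model and returns the single row the
#' meta-regression consumes: log(SD), log(Mean), the delta-method variance
#' of log(SD), and the arm's counts.
#'
#' @param trial_id Trial identifier.
#' @param treatment 0 for placebo, 1 for verum (active treatment).
#' @param ipd Arm-level individual participant data.
#' @return One-row data frame with columns \code{trial_id},
#'   \code{treatment}, \code{log_sd}, \code{log_mean}, \code{var_log_sd},
#'   \code{n}, \code{n_events}.
#' @export
arm_summary <- function(trial_id, treatment, ipd) {
  stopifnot(length(trial_id) == 1, treatment %in% c(0, 1))
  fit <- fit_weibull(ipd)
  data.frame(
    trial_id = as.character(trial_id),
    treatment = as.integer(treatment),
    log_sd = log_sd(fit),
    log_mean = log_mean(fit),
    var_log_sd = var_log_sd(fit),
    n = fit$n,
    n_events = fit$n_events,
    stringsAsFactors = FALSE
  )
}
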