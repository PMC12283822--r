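test_that("censored Weibull MLE matches the brute-force grid oracle on small samples", {
  cases <- list(
    data.frame(time = c(1, 2, 3, 4, 5), status = 1),
    data.frame(time = c(2, 3, 5, 8, 13, 21), status = c(1, 1, 0, 1, 1, 1)),
    simulate_arm(arm_truth(1.5, 20, 25, 0.01, 20), seed = 8)
  )
  for (ipd in cases) {
    if (sum(ipd$status) < 2) next
    fit <- fit_weibull(ipd)
    oracle <- grid_search_weibull(ipd$time, ipd$status)
    expect_equal(fit$shape, oracle[["shape"]], tolerance = 1e-3)
    expect_equal(fit$scale, oracle[["scale"]], tolerance = 1e-3)
    expect_lt(fit$gradient_norm, 1e-6)
  }
})

test_that("simulation recovery: estimates fall within delta-method uncertainty", {
  tr <- arm_truth(1.3, 60, 69.3, 0, 10000) # ~30% administrative censoring
  ipd <- simulate_arm(tr, seed = 15)
  expect_gt(mean(1 - ipd$status), 0.25)
  fit <- fit_weibull(ipd)
  se_logk <- sqrt(fit$cov_log_params[1, 1])
  se_loglam <- sqrt(fit$cov_log_params[2, 2])
  expect_lt(abs(log(fit$shape) - log(1.3)), 4 * se_logk)
  expect_lt(abs(log(fit$scale) - log(60)), 4 * se_loglam)
})

test_that("degenerate inputs raise fit errors", {
  expect_error(fit_weibull(data.frame(time = c(3, 3, 3), status = 1)),
               "insufficient events")
  expect_error(fit_weibull(data.frame(time = c(1, 2, 3), status = c(1, 0, 0))),
               "insufficient events")
  expect_error(fit_weibull(data.frame(time = numeric(), status = integer())), "empty")
})

test_that("closed-form moments agree with numerical integration", {
  for (par in list(c(1, 10), c(2, 1), c(0.8, 150), c(1.35, 290))) {
    m <- weibull_moments(list(shape = par[1], scale = par[2]))
    o <- integrate_weibull_moments(par[1], par[2])
    expect_equal(m[["mean"]], o[["mean"]], tolerance = 1e-8)
    expect_equal(m[["sd"]], o[["sd"]], tolerance = 1e-8)
  }
  # exponential special case and the shape-2 values
  expect_equal(weibull_moments(list(shape = 1, scale = 10)),
               c(mean = 10, sd = 10))
  m2 <- weibull_moments(list(shape = 2, scale = 1))
  expect_equal(m2[["mean"]], sqrt(pi) / 2, tolerance = 1e-6)
  expect_equal(m2[["sd"]], sqrt(1 - pi / 4), tolerance = 1e-6)
  # degenerate limit: large shape concentrates at the scale
  m3 <- weibull_moments(list(shape = 200, scale = 5))
  expect_lt(m3[["sd"]], 1e-2 * 5)
  expect_equal(m3[["mean"]], 5, tolerance = 1e-2)
})

test_that("log_sd and log_mean transform the moments", {
  f <- list(shape = 1, scale = exp(1))
  expect_equal(log_sd(f), 1)
  expect_equal(log_mean(f), 1)
  expect_equal(log_sd(list(shape = 2, scale = 1)), log(sqrt(1 - pi / 4)),
               tolerance = 1e-6)
  # SD <= Mean exactly when shape >= 1
  for (k in c(0.5, 0.9, 1, 1.3, 4)) {
    m <- weibull_moments(list(shape = k, scale = 7))
    expect_equal(log_sd(list(shape = k, scale = 7)) <= log_mean(list(shape = k, scale = 7)),
                 m[["sd"]] <= m[["mean"]])
    if (k >= 1) expect_lte(m[["sd"]], m[["mean"]] + 1e-12)
  }
})

test_that("delta-method variance of log(SD) has the exponential closed form", {
  # shape known to be 1 and only the scale estimated from m complete
  # observations: Var(log lambda) = 1/m and d logSD/d loglambda = 1
  m <- 50
  fit <- structure(list(shape = 1, scale = 30,
                        cov_log_params = matrix(c(0, 0, 0, 1 / m), 2, 2)),
                   class = "weibull_fit")
  expect_equal(var_log_sd(fit), 1 / m)
  # positivity for genuine fits
  f <- fit_weibull(simulate_arm(arm_truth(1.2, 90, 60, 0.005, 400), seed = 3))
  expect_gt(var_log_sd(f), 0)
  # analytic gradient of log SD w.r.t. log shape matches finite differences
  g <- survarmeta:::log_sd_grad(1.37)
  eps <- 1e-6
  num <- (log_sd(list(shape = 1.37 * exp(eps), scale = 1)) -
            log_sd(list(shape = 1.37 * exp(-eps), scale = 1))) / (2 * eps)
  expect_equal(g[["log_shape"]], num, tolerance = 1e-6)
})

test_that("bootstrap variance is reproducible and propagates failures", {
  ipd <- simulate_arm(arm_truth(1.3, 100, 50, 0.005, 300), seed = 4)
  b1 <- bootstrap_var_log_sd(ipd, B = 120, seed = 9)
  b2 <- bootstrap_var_log_sd(ipd, B = 120, seed = 9)
  expect_identical(b1, b2)
  expect_gt(b1, 0)
  degenerate <- data.frame(time = rep(2, 20), status = 1)
  expect_error(bootstrap_var_log_sd(degenerate, B = 100, seed = 1))
})

test_that("arm_summary assembles the meta-regression observation", {
  # a placebo arm simulated at log(SD) ~ 5.45 months is summarized near it
  target_sd <- exp(5.45)
  par <- survarmeta:::solve_weibull_from_moments(target_sd / 0.8, target_sd)
  ipd <- simulate_arm(arm_truth(par[["shape"]], par[["scale"]], 48, 0.001, 8000),
                      seed = 6)
  row <- arm_summary("TRIAL", 0, ipd)
  expect_equal(row$treatment, 0L)
  expect_equal(row$trial_id, "TRIAL")
  expect_lt(abs(row$log_sd - 5.45), 4 * sqrt(row$var_log_sd))
  expect_equal(row$n, 8000L)
  # zero-event arm errors; treatment flag passes through
  expect_error(arm_summary("X", 1, data.frame(time = c(1, 2), status = 0)))
  expect_equal(arm_summary("Y", 1, ipd)$treatment, 1L)
})

test_that("MLE agrees with an independent censored-Weibull fitter", {
  # survreg's Weibull parameterization: shape = 1/fit$scale,
  # scale = exp(intercept)
  ipd <- simulate_arm(arm_truth(1.4, 150, 60, 0.003, 900), seed = 12)
  mine <- fit_weibull(ipd)
  sr <- survival::survreg(survival::Surv(time, status) ~ 1, data = ipd,
                          dist = "weibull")
  expect_equal(mine$shape, 1 / sr$scale, tolerance = 1e-5)
  expect_equal(mine$scale, unname(exp(coef(sr))), tolerance = 1e-5)
})
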