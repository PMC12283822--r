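test_that("simulate_arm draws censored Weibull data with the stated mechanism", {
  # exponential special case: shape 1, no censoring
  tr <- arm_truth(shape = 1, scale = 50, max_follow_up = 1e9, dropout_rate = 0, n = 100)
  ipd <- simulate_arm(tr, seed = 1)
  expect_equal(nrow(ipd), 100)
  expect_true(all(ipd$status == 1))
  expect_true(all(ipd$time > 0))
  expect_lt(abs(mean(ipd$time) - 50), 4 * 50 / sqrt(100))

  # administrative event fraction matches the closed-form Weibull CDF
  tr2 <- arm_truth(1.2, 300, 36, 0, 1000)
  ipd2 <- simulate_arm(tr2, seed = 2)
  p <- 1 - exp(-(36 / 300)^1.2)
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(mean(ipd2$status) - p), 3 * se)
  expect_true(all(ipd2$time <= 36))

  # administrative censoring dominating
  tr3 <- arm_truth(2, 10, 0.001, 0, 10)
  ipd3 <- simulate_arm(tr3, seed = 3)
  expect_equal(nrow(ipd3), 10)
  expect_true(all(ipd3$status == 0))
  expect_true(all(ipd3$time == 0.001))

  # determinism and parameter validation
  expect_identical(simulate_arm(tr2, seed = 7), simulate_arm(tr2, seed = 7))
  expect_error(arm_truth(-1, 10, 10, 0, 5), "positive")
  expect_error(arm_truth(1, 10, 10, 0, 0), "positive integer")
})

test_that("simulated moments converge to the closed-form Weibull moments", {
  tr <- arm_truth(1.4, 120, 1e9, 0, 10000)
  ipd <- simulate_arm(tr, seed = 11)
  m_true <- 120 * gamma(1 + 1 / 1.4)
  s_true <- 120 * sqrt(gamma(1 + 2 / 1.4) - gamma(1 + 1 / 1.4)^2)
  expect_lt(abs(mean(ipd$time) - m_true), 4 * s_true / sqrt(10000))
  # SE of the sample SD ~ sd/sqrt(2n) under approximate normality; use the
  # generous kurtosis-robust factor 2
  expect_lt(abs(sd(ipd$time) - s_true), 4 * 2 * s_true / sqrt(2 * 10000))
})

test_that("simulate_portfolio builds the configured trial structure", {
  # null configuration: identical arms
  pt0 <- portfolio_truth(n_trials = 10, beta_treatment = 0, tau = 0,
                         n_per_arm = 500, seed = 4)
  po0 <- simulate_portfolio(pt0)
  expect_length(po0, 10)
  for (tr in po0) {
    expect_identical(tr$placebo$truth, tr$verum$truth)
    expect_true(all(tr$placebo$ipd$time <= tr$placebo$truth$max_follow_up))
  }

  # treatment effect enters the targets exactly, trial by trial
  pt <- portfolio_truth(n_trials = 10, beta_treatment = -0.036, tau = 0.05, seed = 1)
  po <- simulate_portfolio(pt)
  for (tr in po) {
    expect_equal(tr$targets$log_sd_verum - tr$targets$log_sd_placebo, -0.036)
    # solved Weibull parameters reproduce the targets
    mp <- weibull_moments(tr$placebo$truth)
    mv <- weibull_moments(tr$verum$truth)
    expect_equal(log(mp[["sd"]]), tr$targets$log_sd_placebo, tolerance = 1e-8)
    expect_equal(log(mv[["sd"]]), tr$targets$log_sd_verum, tolerance = 1e-8)
    # common mean time to death in both arms
    expect_equal(mp[["mean"]], mv[["mean"]], tolerance = 1e-8)
  }

  # determinism
  expect_identical(simulate_portfolio(pt, seed = 1), simulate_portfolio(pt, seed = 1))

  # unsolvable targets error
  expect_error(survarmeta:::solve_weibull_from_moments(10, -1), "parameter error")
})

test_that("render_km produces the product-limit step coordinates and risk table", {
  # four events, hand-computed steps
  r <- render_km(data.frame(time = 1:4, status = 1), risk_times = c(0, 5))
  expect_equal(km_value(r$curve, c(0.5, 1, 2, 3, 4)), c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(r$total_events, 4L)
  expect_equal(r$risk$n_at_risk, c(4L, 0L))

  # censored subject reduces the at-risk denominator
  r2 <- render_km(data.frame(time = c(1, 2, 2.5, 3), status = c(1, 1, 0, 1)),
                  risk_times = c(0, 4))
  expect_equal(km_value(r2$curve, c(1, 2, 3)), c(0.75, 0.5, 0))

  # all censored: flat at 1
  r3 <- render_km(data.frame(time = rep(5, 8), status = 0), risk_times = c(0, 6))
  expect_true(all(r3$curve$survival == 1))
  expect_equal(r3$total_events, 0L)

  expect_error(render_km(data.frame(time = numeric(), status = integer())), "empty")
  expect_error(render_km(data.frame(time = 1, status = 1), risk_times = c(1, 2)),
               "start at 0")
})

test_that("perturb_digitization preserves survival-curve structure", {
  r <- render_km(simulate_arm(arm_truth(1.3, 100, 48, 0.002, 400), seed = 5))
  cv <- r$curve
  expect_identical(perturb_digitization(cv, 0), cv)
  pz <- perturb_digitization(cv, 0.005, seed = 2)
  expect_true(all(diff(pz$survival) <= 1e-12))
  expect_true(all(pz$survival >= 0 & pz$survival <= 1))
  expect_equal(pz$survival[pz$time == 0], rep(1, sum(pz$time == 0)))
  expect_identical(pz, perturb_digitization(cv, 0.005, seed = 2))
  expect_false(identical(pz$survival, cv$survival))
})
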