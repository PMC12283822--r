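# Small deterministic arm tables for structural checks.
toy_arms <- function(delta = 0, n_trials = 5, seed = 2) {
  set.seed(seed)
  base <- runif(n_trials, 5.2, 5.7)
  lm_ <- runif(n_trials, 5.4, 6.0)
  data.frame(
    trial_id = rep(sprintf("T%02d", 1:n_trials), each = 2),
    treatment = rep(c(0L, 1L), n_trials),
    log_sd = as.vector(rbind(base, base + delta)),
    log_mean = rep(lm_, each = 2),
    var_log_sd = rep(0.01, 2 * n_trials),
    n = 1000L, n_events = 100L
  )
}

test_that("identical arms give a treatment coefficient of exactly zero", {
  fit <- fit_primary(toy_arms(delta = 0))
  expect_equal(unname(fit$coefficients["treatment"]), 0, tolerance = 1e-12)
})

test_that("with tau2 = 0 and equal weights the fit is the closed-form WLS solution", {
  arms <- toy_arms(delta = -0.04)
  arms$log_sd <- arms$log_sd + rnorm(nrow(arms), 0, 0.05) # break symmetry
  fit <- fit_primary(arms, tau2 = 0)
  X <- cbind(1, arms$treatment, arms$log_mean)
  beta_ne <- drop(solve(t(X) %*% X, t(X) %*% arms$log_sd)) # normal equations
  expect_equal(unname(fit$coefficients), beta_ne, tolerance = 1e-8)
  # and the Wald machinery is consistent with the stated CI definition
  expect_equal(unname(fit$ci95[, "low"]), unname(fit$coefficients - 1.96 * fit$se))
  expect_equal(unname(fit$ci95[, "high"]), unname(fit$coefficients + 1.96 * fit$se))
})

test_that("REML profile attains its maximum among all grid candidates", {
  arms <- portfolio_arm_summaries(quick_portfolio(seed = 5, n_trials = 6))
  fit <- fit_primary(arms)
  expect_true(all(fit$reml >= fit$profile$reml - 1e-9))
  expect_gte(fit$tau2, 0)
})

test_that("estimates are invariant to trial ordering and relabeling", {
  arms <- portfolio_arm_summaries(quick_portfolio(seed = 9, n_trials = 5))
  fit1 <- fit_primary(arms)
  perm <- sample(nrow(arms))
  arms2 <- arms[perm, ]
  fit2 <- fit_primary(arms2)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-9)
  expect_equal(fit1$tau2, fit2$tau2, tolerance = 1e-8)
  arms3 <- arms
  arms3$trial_id <- paste0("XX_", arms3$trial_id)
  fit3 <- fit_primary(arms3)
  expect_equal(fit1$coefficients, fit3$coefficients, tolerance = 1e-9)
})

test_that("the REML engine agrees with an independent mixed-model implementation", {
  skip_if_not_installed("metafor")
  arms <- portfolio_arm_summaries(quick_portfolio(seed = 13, n_trials = 8))
  fit <- fit_primary(arms)
  mf <- metafor::rma.mv(log_sd ~ treatment + log_mean, V = var_log_sd,
                        random = ~ 1 | trial_id, data = arms, method = "REML")
  expect_equal(unname(fit$coefficients), as.vector(mf$beta), tolerance = 1e-5)
  expect_equal(unname(fit$se), as.vector(mf$se), tolerance = 1e-4)
  expect_equal(fit$tau2, mf$sigma2, tolerance = 1e-5)
})

test_that("degenerate designs raise errors", {
  arms <- toy_arms()
  arms$log_mean <- 5.5 # constant adjustment covariate
  expect_error(fit_primary(arms), "singular")
  expect_error(fit_primary(toy_arms()[1:2, ]), "at least 2 trials")
  one_armed <- toy_arms()[-2, ]
  expect_error(fit_primary(one_armed), "one placebo and one verum")
  expect_error(validate_arms <- fit_primary(transform(toy_arms(), var_log_sd = 0)),
               "positive")
})

test_that("interaction models add centered predictor and treatment terms", {
  po <- quick_portfolio(seed = 17, n_trials = 6)
  arms <- portfolio_arm_summaries(po)
  covs <- portfolio_covariates(po)
  fit <- fit_interaction(arms, covs, "mean_hba1c")
  expect_true(all(c("mean_hba1c", "treatment:mean_hba1c") %in% names(fit$coefficients)))
  # constant predictor across trials is inestimable
  covs2 <- covs
  covs2$mean_hba1c <- 8
  expect_error(fit_interaction(arms, covs2, "mean_hba1c"), "singular")
  # all-missing and not-enough-trials errors
  covs3 <- covs
  covs3$mean_hba1c <- NA
  expect_error(fit_interaction(arms, covs3, "mean_hba1c"), "all trials")
  covs4 <- covs
  covs4$mean_hba1c[1:4] <- NA
  expect_error(fit_interaction(arms, covs4, "mean_hba1c"), "fewer than 3")
})

test_that("drug class enters as two indicator contrasts with DPP-4 reference", {
  po <- quick_portfolio(seed = 19, n_trials = 6)
  arms <- portfolio_arm_summaries(po)
  covs <- portfolio_covariates(po)
  fit <- fit_interaction(arms, covs, "drug_class")
  expect_true(all(c("drug_classGLP-1", "drug_classSGLT2",
                    "treatment:drug_classGLP-1", "treatment:drug_classSGLT2")
                  %in% names(fit$coefficients)))
})

test_that("the predictor screen reports every predictor in order and tolerates missingness", {
  po <- quick_portfolio(seed = 23, n_trials = 6)
  arms <- portfolio_arm_summaries(po)
  covs <- portfolio_covariates(po)
  # mimic missing lipid values in a subset of trials
  covs$mean_chol[covs$trial_id %in% c("T01", "T02", "T03")] <- NA
  scr <- suppressMessages(screen_all_predictors(arms, covs))
  expect_equal(unique(scr$predictor), survarmeta:::meta_predictors())
  chol <- scr[scr$predictor == "mean_chol", ]
  expect_equal(chol$n_trials, 3L)
  full <- scr[scr$predictor == "mean_age", ]
  expect_equal(full$n_trials, 6L)
  # per-predictor failure is recorded, not fatal
  covs$mean_trig <- NA
  scr2 <- suppressMessages(screen_all_predictors(arms, covs))
  expect_false(is.na(scr2$error[scr2$predictor == "mean_trig"]))
})

test_that("subgroup fits restrict to one drug class and flag small samples", {
  po <- quick_portfolio(seed = 29, n_trials = 8)
  arms <- portfolio_arm_summaries(po)
  covs <- portfolio_covariates(po)
  fit <- subgroup_fit(arms, covs, "SGLT2")
  ids <- covs$trial_id[covs$drug_class == "SGLT2"]
  expect_equal(fit$n_trials, length(ids))
  expect_true(fit$n_trials < 4 || !fit$small_sample)
  # identical arms within the class give beta1 = 0
  sub_ids <- covs$trial_id[covs$drug_class == "GLP-1"]
  arms0 <- arms[arms$trial_id %in% sub_ids, ]
  pl <- arms0[arms0$treatment == 0, ]
  for (col in c("log_sd", "log_mean", "var_log_sd")) {
    arms0[[col]] <- pl[[col]][match(arms0$trial_id, pl$trial_id)]
  }
  fit0 <- subgroup_fit(arms0, covs, "GLP-1")
  expect_equal(unname(fit0$coefficients["treatment"]), 0, tolerance = 1e-10)
  # single-trial class errors
  covs_single <- covs
  covs_single$drug_class <- "SGLT2"
  covs_single$drug_class[1] <- "DPP-4"
  expect_error(subgroup_fit(arms, covs_single, "DPP-4"), "fewer than 2")
})
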