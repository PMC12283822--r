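# Inverse-variance-weighted random-intercept meta-regression of arm-level
# log(SD) on treatment, adjusted for log(Mean), with per-predictor
# treatment-interaction screens.
#
# Model: y_ij = x_ij' beta + b_i + e_ij, with b_i ~ N(0, tau^2) per trial
# and e_ij ~ N(0, v_ij) where the sampling variances v_ij = Var(log SD)
# are treated as known (the meta-analytic convention). tau^2 is estimated
# by restricted maximum likelihood over a grid-refined 1-D profile; fixed
# effects by generalized least squares at the optimum, with Wald z
# inference.

meta_predictors <- function() {
  c("mean_age", "pct_male", "mean_bmi", "mean_hba1c", "mean_duration",
    "mean_egfr", "mean_sbp", "mean_chol", "mean_trig", "median_follow_up",
    "year", "drug_class")
}

validate_arms <- function(arms) {
  if (!is.data.frame(arms)) stop("`arms` must be a data frame", call. = FALSE)
  need <- c("trial_id", "treatment", "log_sd", "log_mean", "var_log_sd")
  miss <- setdiff(need, names(arms))
  if (length(miss)) stop("`arms` lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!all(arms$treatment %in% c(0, 1)))
    stop("`treatment` must be coded 0 (placebo) / 1 (verum)", call. = FALSE)
  if (any(!is.finite(arms$var_log_sd)) || any(arms$var_log_sd <= 0))
    stop("all `var_log_sd` must be positive", call. = FALSE)
  arms
}

# restricted log-likelihood of tau2 (constants dropped)
reml_ll <- function(tau2, y, X, v, trial) {
  n <- length(y)
  V <- diag(v, n)
  for (id in unique(trial)) {
    idx <- which(trial == id)
    V[idx, idx] <- V[idx, idx] + tau2
  }
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  ldV <- 2 * sum(log(diag(R)))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  A <- crossprod(X, Vi_X)
  b <- crossprod(X, Vi_y)
  beta <- solve(A, b)
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  q <- as.numeric(crossprod(r, Vi_r))
  ldA <- determinant(A, logarithm = TRUE)$modulus
  -0.5 * (ldV + as.numeric(ldA) + q)
}

meta_gls <- function(tau2, y, X, v, trial) {
  n <- length(y)
  V <- diag(v, n)
  for (id in unique(trial)) {
    idx <- which(trial == id)
    V[idx, idx] <- V[idx, idx] + tau2
  }
  R <- chol(V)
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  A <- crossprod(X, Vi_X)
  beta <- drop(solve(A, crossprod(X, Vi_y)))
  vc <- solve(A)
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(beta = beta, vcov = vc)
}

# Fit the weighted random-intercept model for a given design matrix.
meta_fit_engine <- function(y, X, v, trial, tau2_fixed = NULL, model = "primary") {
  if (qr(X)$rank < ncol(X))
    stop("singular design: the model matrix is rank deficient", call. = FALSE)
  profile <- NULL
  warn_bound <- FALSE
  if (is.null(tau2_fixed)) {
    tau2_max <- max(10 * stats::var(y), 10 * max(v), 1e-2)
    grid <- c(0, exp(seq(log(1e-7), log(tau2_max), length.out = 80)))
    ll <- vapply(grid, function(t2) reml_ll(t2, y, X, v, trial), numeric(1))
    i <- which.max(ll)
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(function(t2) reml_ll(t2, y, X, v, trial),
                           c(lo, hi), maximum = TRUE, tol = 1e-12)
    if (opt$objective >= ll[i]) {
      tau2 <- opt$maximum
      ll_at <- opt$objective
    } else {
      tau2 <- grid[i]
      ll_at <- ll[i]
    }
    if (tau2 < 1e-10) { tau2 <- 0; ll_at <- reml_ll(0, y, X, v, trial) }
    warn_bound <- (tau2 > 0.999 * tau2_max)
    if (warn_bound)
      warning("tau^2 estimate at the upper search bound; heterogeneity may be unidentified")
    profile <- data.frame(tau2 = grid, reml = ll)
  } else {
    stopifnot(tau2_fixed >= 0)
    tau2 <- tau2_fixed
    ll_at <- reml_ll(tau2, y, X, v, trial)
  }
  g <- meta_gls(tau2, y, X, v, trial)
  se <- sqrt(diag(g$vcov))
  est <- g$beta
  ci <- cbind(low = est - 1.96 * se, high = est + 1.96 * se)
  rownames(ci) <- names(est)
  structure(list(
    model = model,
    coefficients = est, se = se, ci95 = ci, vcov = g$vcov,
    tau2 = tau2, reml = ll_at, profile = profile,
    n_arms = length(y), n_trials = length(unique(trial)),
    converged = !warn_bound,
    trial = trial, y = y, X = X, v = v
  ), class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Weighted random-intercept meta-regression (%s)\n", x$model))
  cat(sprintf("  %d arms in %d trials; tau^2 = %.5g\n", x$n_arms, x$n_trials, x$tau2))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    ci_low = x$ci95[, "low"], ci_high = x$ci95[, "high"])
  print(round(tab, 4))
  invisible(x)
}

#' Primary variability meta-regression
#'
#' Fits the weighted random-intercept model with arm-level log(SD) of time
#' to death as outcome, treatment (verum vs placebo) as the covariate of
#' central interest and log(Mean) as adjustment, each observation weighted
#' by the inverse of its estimated Var(log SD). A treatment coefficient of
#' 0 means equal variability in verum and placebo arms, i.e. no evidence
#' of treatment-effect heterogeneity.
#'
#' @param arms Data frame of \code{\link{arm_summary}} rows (both arms of
#'   at least 2 trials).
#' @param tau2 Optional fixed value for the random-intercept variance;
#'   \code{NULL} (default) estimates it by REML.
#' @return Object of class \code{meta_fit} with elements
#'   \code{coefficients} (\code{intercept}, \code{treatment},
#'   \code{log_mean}), \code{se}, \code{ci95}, \code{tau2}, \code{profile}
#'   (the REML grid), \code{n_arms}, \code{n_trials}, \code{converged}.
#' @export
fit_primary <- function(arms, tau2 = NULL) {
  arms <- validate_arms(arms)
  tab <- table(arms$trial_id, arms$treatment)
  if (nrow(tab) < 2) stop("need at least 2 trials", call. = FALSE)
  if (!all(tab == 1))
    stop("primary model expects exactly one placebo and one verum arm per trial",
         call. = FALSE)
  X <- cbind(intercept = 1, treatment = arms$treatment, log_mean = arms$log_mean)
  meta_fit_engine(arms$log_sd, X, arms$var_log_sd, as.character(arms$trial_id),
                  tau2_fixed = tau2, model = "primary")
}

# Merge arm rows with the covariate table (by trial, and by arm when the
# covariate table is arm-specific).
merge_covariates <- function(arms, covariates) {
  if (!is.data.frame(covariates)) stop("`covariates` must be a data frame", call. = FALSE)
  if (!"trial_id" %in% names(covariates))
    stop("`covariates` needs a `trial_id` column", call. = FALSE)
  by <- "trial_id"
  if ("treatment" %in% names(covariates)) by <- c("trial_id", "treatment")
  merged <- merge(arms, covariates, by = by, sort = FALSE)
  merged[order(match(merged$trial_id, unique(arms$trial_id)), merged$treatment), ]
}

#' Treatment-by-predictor interaction model
#'
#' Extends the primary model by one clinical predictor's main effect and
#' its interaction with treatment. Continuous predictors are centered at
#' the inverse-variance-weighted mean of the included arms (centering
#' stabilizes the main effects without changing the interaction
#' estimate); \code{drug_class} enters as two indicator contrasts with
#' DPP-4 as reference. Arms from trials missing the predictor are dropped
#' (count recorded in the result).
#'
#' @param arms Data frame of arm observations.
#' @param covariates Covariate table with \code{trial_id} and the predictor
#'   columns (per trial, or per arm if it has a \code{treatment} column).
#' @param predictor One of \code{meta_predictors()}.
#' @param tau2 Optional fixed random-intercept variance.
#' @return A \code{meta_fit}; interaction terms are named
#'   \code{treatment:<predictor>}. Element \code{n_trials_dropped} counts
#'   complete-case exclusions.
#' @export
fit_interaction <- function(arms, covariates, predictor, tau2 = NULL) {
  arms <- validate_arms(arms)
  stopifnot(length(predictor) == 1)
  if (!predictor %in% names(covariates))
    stop(sprintf("predictor `%s` not found in covariates", predictor), call. = FALSE)
  m <- merge_covariates(arms, covariates)
  x <- m[[predictor]]
  ok <- tapply(!is.na(x), m$trial_id, all)
  keep_trials <- names(ok)[ok]
  drop_trials <- setdiff(unique(m$trial_id), keep_trials)
  # complete-case per predictor: a trial missing the value loses both arms
  m <- m[m$trial_id %in% keep_trials, , drop = FALSE]
  n_tr <- length(unique(m$trial_id))
  if (n_tr == 0) stop("predictor missing for all trials", call. = FALSE)
  if (n_tr < 3) stop("fewer than 3 trials with the predictor observed", call. = FALSE)
  if (length(drop_trials))
    message(sprintf("fit_interaction(%s): dropped %d trial(s) with missing values",
                    predictor, length(drop_trials)))
  if (predictor == "drug_class") {
    f <- factor(m$drug_class, levels = c("DPP-4", "GLP-1", "SGLT2"))
    if (any(is.na(f))) stop("unknown drug class level", call. = FALSE)
    Xp <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(Xp) <- paste0("drug_class", levels(f)[-1])
  } else {
    xc <- m[[predictor]]
    w <- 1 / m$var_log_sd
    xc <- xc - sum(w * xc) / sum(w)
    Xp <- matrix(xc, ncol = 1, dimnames = list(NULL, predictor))
  }
  Xint <- Xp * m$treatment
  colnames(Xint) <- paste0("treatment:", colnames(Xp))
  X <- cbind(intercept = 1, treatment = m$treatment, log_mean = m$log_mean,
             Xp, Xint)
  fit <- meta_fit_engine(m$log_sd, X, m$var_log_sd, as.character(m$trial_id),
                         tau2_fixed = tau2,
                         model = paste0("interaction:", predictor))
  fit$predictor <- predictor
  fit$n_trials_dropped <- length(drop_trials)
  fit
}

#' Screen all clinical predictors for treatment interactions
#'
#' Runs \code{\link{fit_interaction}} for each of the 12 clinical
#' predictors (baseline means, median follow-up, trial year and drug
#' class, in that order) and tabulates the interaction terms. Per-predictor
#' failures are recorded in the table rather than raised.
#'
#' @param arms Data frame of arm observations.
#' @param covariates Covariate table.
#' @return Data frame with one row per interaction term: \code{predictor},
#'   \code{term}, \code{estimate}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{tau2}, \code{n_trials}, \code{n_arms},
#'   \code{error} (NA when the fit succeeded).
#' @export
screen_all_predictors <- function(arms, covariates) {
  out <- list()
  for (p in meta_predictors()) {
    row <- tryCatch({
      fit <- fit_interaction(arms, covariates, p)
      ii <- grep("^treatment:", names(fit$coefficients))
      data.frame(
        predictor = p,
        term = names(fit$coefficients)[ii],
        estimate = unname(fit$coefficients[ii]),
        se = unname(fit$se[ii]),
        ci_low = unname(fit$ci95[ii, "low"]),
        ci_high = unname(fit$ci95[ii, "high"]),
        tau2 = fit$tau2,
        n_trials = fit$n_trials,
        n_arms = fit$n_arms,
        error = NA_character_,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(predictor = p, term = NA_character_, estimate = NA_real_,
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 tau2 = NA_real_, n_trials = NA_integer_, n_arms = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    out[[p]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Primary model within one drug class
#'
#' Restricts the primary meta-regression to the trials of a single drug
#' class. With few trials the random-intercept variance and the Wald
#' standard errors are poorly identified; the returned object carries a
#' \code{small_sample} flag when fewer than 4 trials contribute.
#'
#' @param arms Data frame of arm observations.
#' @param covariates Covariate table containing \code{drug_class}.
#' @param drug_class One of \code{"DPP-4"}, \code{"GLP-1"}, \code{"SGLT2"}.
#' @param tau2 Optional fixed random-intercept variance.
#' @return A \code{meta_fit} with elements \code{drug_class} and
#'   \code{small_sample}.
#' @export
subgroup_fit <- function(arms, covariates, drug_class, tau2 = NULL) {
  stopifnot(drug_class %in% c("DPP-4", "GLP-1", "SGLT2"))
  arms <- validate_arms(arms)
  if (!"drug_class" %in% names(covariates))
    stop("`covariates` needs a `drug_class` column", call. = FALSE)
  ids <- unique(covariates$trial_id[covariates$drug_class == drug_class])
  sub <- arms[arms$trial_id %in% ids, , drop = FALSE]
  if (length(unique(sub$trial_id)) < 2)
    stop(sprintf("fewer than 2 trials in drug class %s", drug_class), call. = FALSE)
  fit <- fit_primary(sub, tau2 = tau2)
  fit$model <- paste0("subgroup:", drug_class)
  fit$drug_class <- drug_class
  fit$small_sample <- fit$n_trials < 4
  if (fit$small_sample)
    fit$se_note <- "standard errors unreliable: fewer than 4 trials in subgroup"
  fit
}
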