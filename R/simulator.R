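# Synthetic two-arm cardiovascular-outcome-trial generator with known
# ground truth. Event times are Weibull; censoring is administrative at
# the trial's maximum follow-up plus independent exponential dropout;
# between-trial heterogeneity enters as a normal random intercept on the
# target log(SD) scale and the treatment effect shifts the verum arm's
# target log(SD).

#' Ground truth for a single trial arm
#'
#' @param shape Weibull shape k (> 0).
#' @param scale Weibull scale lambda in months (> 0).
#' @param max_follow_up Administrative censoring time in months (> 0).
#' @param dropout_rate Hazard (per month) of independent exponential
#'   random censoring; 0 disables dropout.
#' @param n Number of participants (>= 1).
#' @return Object of class \code{arm_truth}.
#' @export
arm_truth <- function(shape, scale, max_follow_up, dropout_rate = 0, n) {
  stopifnot(is.numeric(shape), length(shape) == 1, is.finite(shape),
            is.numeric(scale), length(scale) == 1, is.finite(scale),
            is.numeric(max_follow_up), length(max_follow_up) == 1,
            is.numeric(dropout_rate), length(dropout_rate) == 1,
            is.numeric(n), length(n) == 1)
  if (shape <= 0 || scale <= 0) stop("Weibull parameters must be positive", call. = FALSE)
  if (max_follow_up <= 0) stop("`max_follow_up` must be positive", call. = FALSE)
  if (dropout_rate < 0) stop("`dropout_rate` must be non-negative", call. = FALSE)
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  structure(list(shape = shape, scale = scale, max_follow_up = max_follow_up,
                 dropout_rate = dropout_rate, n = as.integer(n)),
            class = "arm_truth")
}

#' Simulate one trial arm
#'
#' Each participant's observed time is the minimum of the Weibull event
#' time, an exponential dropout time and the administrative cutoff; the
#' event indicator is 1 exactly when the event time attains the minimum.
#'
#' @param truth An \code{\link{arm_truth}}.
#' @param seed Optional integer seed (caller's RNG state restored). When
#'   \code{NULL} the current RNG stream is used, so nested simulations
#'   remain reproducible from a single upstream seed.
#' @return Data frame with columns \code{time}, \code{status}.
#' @export
simulate_arm <- function(truth, seed = NULL) {
  if (!inherits(truth, "arm_truth")) truth <- do.call(arm_truth, truth)
  with_seed(seed, {
    t_ev <- stats::rweibull(truth$n, shape = truth$shape, scale = truth$scale)
    t_cen <- if (truth$dropout_rate > 0)
      stats::rexp(truth$n, rate = truth$dropout_rate) else Inf
    t_cen <- pmin(t_cen, truth$max_follow_up)
    time <- pmin(t_ev, t_cen)
    # rweibull can return exact 0 only with probability 0; guard anyway
    time <- pmax(time, .Machine$double.eps)
    data.frame(time = time, status = as.integer(t_ev <= t_cen))
  })
}

# Squared coefficient of variation of a Weibull law as a function of shape,
# evaluated on the log-gamma scale for stability at extreme shapes.
wb_cv <- function(shape) sqrt(exp(lgamma(1 + 2 / shape) - 2 * lgamma(1 + 1 / shape)) - 1)

# Solve (shape, scale) from target mean and SD of the event-time law.
# CV = SD/Mean is strictly decreasing in shape, so the solve is 1-D.
solve_weibull_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || !is.finite(sd) || mean <= 0 || sd <= 0)
    stop("parameter error: target mean and SD must be positive", call. = FALSE)
  cv <- sd / mean
  lo <- 0.08; hi <- 300
  if (cv >= wb_cv(lo) || cv <= wb_cv(hi))
    stop(sprintf("parameter error: coefficient of variation %.4g outside the solvable range", cv),
         call. = FALSE)
  root <- stats::uniroot(function(lk) log(wb_cv(exp(lk))) - log(cv),
                         lower = log(lo), upper = log(hi), tol = 1e-12)
  shape <- exp(root$root)
  scale <- exp(log(mean) - lgamma(1 + 1 / shape))
  c(shape = shape, scale = scale)
}

# Baseline covariate ranges mirroring published summaries of the ten
# large cardiovascular outcome trials (min-max across arms).
default_covariate_ranges <- function() {
  list(
    mean_age = c(61.0, 66.2),
    pct_male = c(53.4, 72.0),
    mean_bmi = c(28.7, 32.5),
    mean_hba1c = c(7.2, 8.7),
    mean_duration = c(7.1, 16.0),
    mean_egfr = c(54.5, 85.4),
    mean_sbp = c(134.8, 140.6),
    mean_chol = c(153.9, 180.9),
    mean_trig = c(141.6, 198.8),
    year = c(2013, 2019)
  )
}

#' Ground truth for a simulated trial portfolio
#'
#' Defines the study conditions of a synthetic portfolio of two-arm
#' placebo-controlled trials: the true treatment effect on log(SD), the
#' between-trial heterogeneity, arm sizes, censoring, and the covariate
#' generator.
#'
#' @param n_trials Number of trials (>= 2).
#' @param beta_treatment True verum-minus-placebo difference in log(SD).
#' @param tau SD of the trial-level random intercept on log(SD) (>= 0).
#' @param base_log_sd_range Interval for the trial baseline log(SD) of
#'   time to death (months scale); the default brackets the values seen
#'   in large cardiovascular outcome trials.
#' @param cv_range Interval for the trial-level coefficient of variation
#'   SD/Mean of the event-time law (determines the Weibull shape,
#'   roughly 1.1-1.5 over the default range).
#' @param follow_up_range Interval (months) for the administrative
#'   censoring time of a trial.
#' @param dropout_rate Exponential dropout hazard per month, shared by all
#'   arms (CVOT dropout is low; default 0.001/month).
#' @param n_range Interval for per-arm sample sizes (drawn uniformly).
#' @param n_per_arm Optional fixed per-arm size overriding \code{n_range}.
#' @param covariate_ranges Named list of min/max pairs for the arm-level
#'   baseline covariates (uniform draws); see
#'   \code{default_covariate_ranges}.
#' @param drug_classes Optional character vector (length \code{n_trials})
#'   of drug classes; default allocates DPP-4 / GLP-1 / SGLT2 in
#'   proportions 3:3:4.
#' @param interaction_predictor Optional covariate name whose value
#'   modifies the treatment effect (builds in treatment heterogeneity).
#' @param interaction_slope Slope of the built-in treatment-by-predictor
#'   interaction on log(SD), per unit of the predictor.
#' @param interaction_center Predictor value at which the treatment effect
#'   equals \code{beta_treatment}.
#' @param seed Default seed used by \code{\link{simulate_portfolio}}.
#' @return Object of class \code{portfolio_truth}.
#' @export
portfolio_truth <- function(n_trials = 10,
                            beta_treatment = -0.036,
                            tau = 0.05,
                            base_log_sd_range = c(5.2, 5.7),
                            cv_range = c(0.70, 0.90),
                            follow_up_range = c(24, 66),
                            dropout_rate = 0.001,
                            n_range = c(2200, 8600),
                            n_per_arm = NULL,
                            covariate_ranges = default_covariate_ranges(),
                            drug_classes = NULL,
                            interaction_predictor = NULL,
                            interaction_slope = 0,
                            interaction_center = NULL,
                            seed = 1) {
  stopifnot(n_trials >= 2, n_trials == round(n_trials), tau >= 0,
            length(base_log_sd_range) == 2, length(cv_range) == 2,
            length(follow_up_range) == 2, dropout_rate >= 0)
  if (!is.null(drug_classes)) {
    stopifnot(length(drug_classes) == n_trials,
              all(drug_classes %in% c("DPP-4", "GLP-1", "SGLT2")))
  }
  if (!is.null(interaction_predictor)) {
    stopifnot(interaction_predictor %in% names(covariate_ranges))
    if (is.null(interaction_center))
      interaction_center <- mean(covariate_ranges[[interaction_predictor]])
  }
  structure(list(
    n_trials = as.integer(n_trials), beta_treatment = beta_treatment,
    tau = tau, base_log_sd_range = base_log_sd_range, cv_range = cv_range,
    follow_up_range = follow_up_range, dropout_rate = dropout_rate,
    n_range = n_range, n_per_arm = n_per_arm,
    covariate_ranges = covariate_ranges, drug_classes = drug_classes,
    interaction_predictor = interaction_predictor,
    interaction_slope = interaction_slope,
    interaction_center = interaction_center,
    seed = seed
  ), class = "portfolio_truth")
}

#' Simulate a portfolio of two-arm trials
#'
#' For each trial a random intercept \eqn{b_i \sim N(0, \tau^2)} shifts
#' both arms' target log(SD); the verum arm is additionally shifted by the
#' treatment effect (plus any built-in predictor interaction). The trial's
#' mean time to death is common to both arms, so the treatment acts on the
#' variability of the event-time distribution and not on its location;
#' each arm's Weibull shape is solved from its target coefficient of
#' variation and the scale from the target mean.
#'
#' @param truth A \code{\link{portfolio_truth}}.
#' @param seed Integer seed (defaults to the one stored in \code{truth}).
#' @return List of trials (class \code{simulated_portfolio}); each trial is
#'   a list with \code{trial_id}, \code{covariates} (one-row data frame),
#'   \code{placebo}/\code{verum} (each \code{truth} + \code{ipd}) and
#'   \code{targets} (true log(SD)/log(Mean) values).
#' @export
simulate_portfolio <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "portfolio_truth"))
  classes <- truth$drug_classes
  if (is.null(classes))
    classes <- rep_len(c("DPP-4", "GLP-1", "SGLT2", "SGLT2"), truth$n_trials)
  with_seed(seed, {
    trials <- vector("list", truth$n_trials)
    for (i in seq_len(truth$n_trials)) {
      trial_id <- sprintf("T%02d", i)
      b_i <- stats::rnorm(1, 0, truth$tau)
      base <- stats::runif(1, truth$base_log_sd_range[1], truth$base_log_sd_range[2])
      cv <- stats::runif(1, truth$cv_range[1], truth$cv_range[2])
      mfu <- stats::runif(1, truth$follow_up_range[1], truth$follow_up_range[2])
      covs <- lapply(truth$covariate_ranges, function(r) stats::runif(1, r[1], r[2]))
      covs$year <- round(covs$year)
      covs <- data.frame(trial_id = trial_id, drug_class = classes[i],
                         median_follow_up = 0.9 * mfu, covs,
                         stringsAsFactors = FALSE)
      effect <- truth$beta_treatment
      if (!is.null(truth$interaction_predictor)) {
        effect <- effect + truth$interaction_slope *
          (covs[[truth$interaction_predictor]] - truth$interaction_center)
      }
      target_p <- base + b_i
      target_v <- base + b_i + effect
      mean_t <- exp(target_p) / cv
      par_p <- solve_weibull_from_moments(mean_t, exp(target_p))
      par_v <- solve_weibull_from_moments(mean_t, exp(target_v))
      n_p <- if (!is.null(truth$n_per_arm)) truth$n_per_arm
      else round(stats::runif(1, truth$n_range[1], truth$n_range[2]))
      n_v <- if (!is.null(truth$n_per_arm)) truth$n_per_arm
      else round(stats::runif(1, truth$n_range[1], truth$n_range[2]))
      at_p <- arm_truth(par_p[["shape"]], par_p[["scale"]], mfu,
                        truth$dropout_rate, n_p)
      at_v <- arm_truth(par_v[["shape"]], par_v[["scale"]], mfu,
                        truth$dropout_rate, n_v)
      trials[[i]] <- structure(list(
        trial_id = trial_id,
        covariates = covs,
        placebo = list(truth = at_p, ipd = simulate_arm(at_p)),
        verum = list(truth = at_v, ipd = simulate_arm(at_v)),
        targets = list(log_sd_placebo = target_p, log_sd_verum = target_v,
                       log_mean = log(mean_t), random_intercept = b_i)
      ), class = "simulated_trial")
    }
    structure(trials, class = "simulated_portfolio", truth = truth)
  })
}

#' Arm-level covariate table of a simulated portfolio
#'
#' @param portfolio A \code{simulated_portfolio}.
#' @return Data frame, one row per trial, matching the covariate CSV
#'   schema.
#' @export
portfolio_covariates <- function(portfolio) {
  stopifnot(inherits(portfolio, "simulated_portfolio"))
  do.call(rbind, lapply(portfolio, function(tr) tr$covariates))
}

#' Arm-level meta-regression observations of a simulated portfolio
#'
#' Fits the censored Weibull model to every arm's individual records
#' (skipping the curve-rendering/reconstruction stages) and stacks the
#' resulting rows.
#'
#' @param portfolio A \code{simulated_portfolio}.
#' @return Data frame of \code{\link{arm_summary}} rows.
#' @export
portfolio_arm_summaries <- function(portfolio) {
  stopifnot(inherits(portfolio, "simulated_portfolio"))
  do.call(rbind, lapply(portfolio, function(tr) {
    rbind(arm_summary(tr$trial_id, 0, tr$placebo$ipd),
          arm_summary(tr$trial_id, 1, tr$verum$ipd))
  }))
}
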