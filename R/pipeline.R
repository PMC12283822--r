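# Orchestration: simulate (or read digitized inputs) -> reconstruct ->
# fit per-arm Weibull models -> meta-regression, with CSV interchange at
# every stage and a cohort report mirroring a trial-description table.

#' Pipeline configuration
#'
#' Exactly one input source must be active: either a
#' \code{\link{portfolio_truth}} (simulated portfolio) or the paths of
#' digitized curve / risk-table / covariate CSV files.
#'
#' @param simulator A \code{portfolio_truth}, or \code{NULL}.
#' @param curves_csv,risk_csv,covariates_csv Paths to input CSVs
#'   (schemas: \code{trial_id,arm,time_months,survival};
#'   \code{trial_id,arm,time_months,n_at_risk} with optional
#'   \code{total_events}; covariate columns keyed by \code{trial_id}).
#' @param output_dir Directory for intermediate and result files
#'   (\code{NULL}: nothing written).
#' @param seed Integer seed for every stochastic stage.
#' @param risk_interval Risk-table granularity in months for rendering
#'   simulated trials (published figures typically tabulate every 6
#'   months).
#' @param noise_sd Digitization noise added to simulated curves before
#'   reconstruction (0 = exact coordinates).
#' @param use_total_events Pass each arm's total event count to the
#'   reconstruction as a constraint.
#' @param screen Also run the treatment-interaction screen over all
#'   clinical predictors.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulator = NULL, curves_csv = NULL, risk_csv = NULL,
                            covariates_csv = NULL, output_dir = NULL, seed = 1,
                            risk_interval = 6, noise_sd = 0,
                            use_total_events = TRUE, screen = FALSE) {
  real <- !is.null(curves_csv) || !is.null(risk_csv)
  if (is.null(simulator) && !real)
    stop("supply either `simulator` or input CSV paths", call. = FALSE)
  if (!is.null(simulator) && real)
    stop("supply either `simulator` or input CSV paths, not both", call. = FALSE)
  if (real && (is.null(curves_csv) || is.null(risk_csv)))
    stop("real-data input needs both `curves_csv` and `risk_csv`", call. = FALSE)
  if (!is.null(simulator)) stopifnot(inherits(simulator, "portfolio_truth"))
  structure(list(simulator = simulator, curves_csv = curves_csv,
                 risk_csv = risk_csv, covariates_csv = covariates_csv,
                 output_dir = output_dir, seed = seed,
                 risk_interval = risk_interval, noise_sd = noise_sd,
                 use_total_events = use_total_events, screen = screen),
            class = "pipeline_config")
}

#' Aggregate death and observation counts
#'
#' @param rows Data frame with columns \code{deaths}, \code{n} and either
#'   \code{treatment} (0/1) or \code{arm} ("placebo"/"verum").
#' @return Named list of integer totals: per-group deaths and
#'   observations plus the grand totals.
#' @export
summarize_counts <- function(rows) {
  if (nrow(rows) == 0)
    return(list(placebo_deaths = 0L, placebo_observations = 0L,
                verum_deaths = 0L, verum_observations = 0L,
                total_deaths = 0L, total_observations = 0L))
  if (!"treatment" %in% names(rows)) {
    if (!"arm" %in% names(rows))
      stop("`rows` needs a `treatment` or `arm` column", call. = FALSE)
    rows$treatment <- ifelse(tolower(rows$arm) == "verum", 1L, 0L)
  }
  if (any(rows$deaths < 0) || any(rows$n < 0))
    stop("counts must be non-negative", call. = FALSE)
  p <- rows$treatment == 0
  list(
    placebo_deaths = as.integer(sum(rows$deaths[p])),
    placebo_observations = as.integer(sum(rows$n[p])),
    verum_deaths = as.integer(sum(rows$deaths[!p])),
    verum_observations = as.integer(sum(rows$n[!p])),
    total_deaths = as.integer(sum(rows$deaths)),
    total_observations = as.integer(sum(rows$n))
  )
}

#' Descriptive statistics of log(SD) per treatment group
#'
#' Unweighted mean, median, minimum and maximum of the arm-level log(SD)
#' values, separately for placebo and verum arms.
#'
#' @param arms Data frame with columns \code{treatment}, \code{log_sd}.
#' @return Data frame with rows \code{placebo} and \code{verum}.
#' @export
summarize_log_sd <- function(arms) {
  stopifnot(all(c("treatment", "log_sd") %in% names(arms)))
  out <- lapply(c(placebo = 0, verum = 1), function(tr) {
    x <- arms$log_sd[arms$treatment == tr]
    if (length(x) == 0) stop("empty treatment group", call. = FALSE)
    data.frame(mean = mean(x), median = stats::median(x),
               min = min(x), max = max(x))
  })
  res <- do.call(rbind, out)
  res <- cbind(group = rownames(res), res)
  rownames(res) <- NULL
  res
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage, as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Stages: obtain trials (simulate or read), render and optionally perturb
#' the Kaplan-Meier inputs, reconstruct individual records, summarize each
#' arm (Weibull fit, log(SD), log(Mean), Var(log SD)), fit the primary
#' meta-regression and optionally the interaction screen. All intermediate
#' tables are written as CSV when \code{output_dir} is set, and the run is
#' deterministic given the seed.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List with elements \code{cohort} (per-arm rows, count totals,
#'   log(SD) summaries), \code{arms} (meta-regression observations),
#'   \code{primary} (the \code{meta_fit}), \code{screen} (interaction
#'   table or \code{NULL}) and \code{files} (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- character(0)
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(dir)) return(invisible(NULL))
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files[[length(files) + 1]] <<- path
  }

  # --- stage 1: inputs
  t0 <- proc.time()[3]
  if (!is.null(config$simulator)) {
    portfolio <- simulate_portfolio(config$simulator, seed = config$seed)
    covariates <- portfolio_covariates(portfolio)
    units <- list()
    for (tr in portfolio) {
      for (arm in c("placebo", "verum")) {
        a <- tr[[arm]]
        rk <- render_km(a$ipd, risk_times = seq(0, a$truth$max_follow_up + config$risk_interval,
                                                by = config$risk_interval))
        curve <- rk$curve
        if (config$noise_sd > 0) {
          curve <- perturb_digitization(curve, config$noise_sd,
                                        seed = config$seed + 7919 * length(units))
        }
        units[[length(units) + 1]] <- list(
          trial_id = tr$trial_id, arm = arm, curve = curve, risk = rk$risk,
          total_events = rk$total_events)
      }
    }
  } else {
    curves <- utils::read.csv(config$curves_csv, stringsAsFactors = FALSE)
    risks <- utils::read.csv(config$risk_csv, stringsAsFactors = FALSE)
    covariates <- if (!is.null(config$covariates_csv))
      utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE) else NULL
    units <- list()
    for (id in unique(curves$trial_id)) {
      for (arm in unique(curves$arm[curves$trial_id == id])) {
        cu <- curves[curves$trial_id == id & curves$arm == arm, ]
        rk <- risks[risks$trial_id == id & risks$arm == arm, ]
        te <- if ("total_events" %in% names(rk)) rk$total_events[1] else NULL
        if (!is.null(te) && is.na(te)) te <- NULL
        units[[length(units) + 1]] <- list(
          trial_id = id, arm = arm,
          curve = data.frame(time = cu$time_months, survival = cu$survival),
          risk = data.frame(time = rk$time_months, n_at_risk = rk$n_at_risk),
          total_events = te)
      }
    }
    portfolio <- NULL
  }
  curve_rows <- do.call(rbind, lapply(units, function(u)
    data.frame(trial_id = u$trial_id, arm = u$arm,
               time_months = u$curve$time, survival = u$curve$survival)))
  risk_rows <- do.call(rbind, lapply(units, function(u)
    data.frame(trial_id = u$trial_id, arm = u$arm,
               time_months = u$risk$time, n_at_risk = u$risk$n_at_risk,
               total_events = if (is.null(u$total_events)) NA_integer_ else u$total_events)))
  emit(curve_rows, "curves.csv")
  emit(risk_rows, "risk_table.csv")
  if (!is.null(covariates)) emit(covariates, "covariates.csv")
  if (!is.null(config$simulator) && !is.null(dir)) {
    path <- file.path(dir, "truth.json")
    jsonlite::write_json(unclass(config$simulator), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
    files[[length(files) + 1]] <- path
  }
  stage_msg("inputs", t0)

  # --- stage 2: reconstruction
  t0 <- proc.time()[3]
  ipd_rows <- list()
  for (u in units) {
    te <- if (isTRUE(config$use_total_events)) u$total_events else NULL
    ipd <- reconstruct_ipd(u$curve, u$risk, total_events = te)
    ipd_rows[[length(ipd_rows) + 1]] <-
      data.frame(trial_id = u$trial_id, arm = u$arm,
                 time_months = ipd$time, status = ipd$status)
  }
  ipd_all <- do.call(rbind, ipd_rows)
  emit(ipd_all, "ipd.csv")
  stage_msg("reconstruct", t0)

  # --- stage 3: per-arm Weibull summaries
  t0 <- proc.time()[3]
  arms <- do.call(rbind, lapply(ipd_rows, function(df) {
    arm_summary(df$trial_id[1], as.integer(tolower(df$arm[1]) == "verum"),
                data.frame(time = df$time_months, status = df$status))
  }))
  emit(arms, "arm_summary.csv")
  stage_msg("fit-arm", t0)

  # --- stage 4: meta-regression
  t0 <- proc.time()[3]
  primary <- fit_primary(arms)
  screen <- NULL
  if (isTRUE(config$screen) && !is.null(covariates)) {
    screen <- screen_all_predictors(arms, covariates)
    emit(screen, "interaction_screen.csv")
  }
  res <- data.frame(model = primary$model,
                    term = names(primary$coefficients),
                    estimate = unname(primary$coefficients),
                    se = unname(primary$se),
                    ci_low = unname(primary$ci95[, "low"]),
                    ci_high = unname(primary$ci95[, "high"]),
                    tau2 = primary$tau2,
                    n_arms = primary$n_arms, n_trials = primary$n_trials)
  emit(res, "meta_results.csv")
  stage_msg("meta", t0)

  # --- stage 5: cohort report
  per_arm <- do.call(rbind, lapply(seq_along(units), function(i) {
    u <- units[[i]]
    a <- arms[i, ]
    data.frame(trial_id = u$trial_id, arm = u$arm, n = a$n, deaths = a$n_events,
               log_sd = a$log_sd, log_mean = a$log_mean)
  }))
  cohort <- list(rows = per_arm,
                 totals = summarize_counts(
                   data.frame(arm = per_arm$arm, deaths = per_arm$deaths, n = per_arm$n)),
                 log_sd_summary = summarize_log_sd(arms))
  emit(per_arm, "cohort_rows.csv")

  list(cohort = cohort, arms = arms, primary = primary, screen = screen,
       portfolio = portfolio, files = unlist(files))
}

#' Boxplot of arm-level log(SD) by treatment group
#'
#' Unadjusted graphical summary of the variability outcome: one point per
#' arm, arms of the same trial connected, boxes per treatment group.
#'
#' @param arms Data frame with columns \code{trial_id}, \code{treatment},
#'   \code{log_sd}.
#' @return Invisibly, \code{arms}.
#' @export
plot_log_sd <- function(arms) {
  stopifnot(all(c("trial_id", "treatment", "log_sd") %in% names(arms)))
  grp <- factor(ifelse(arms$treatment == 1, "verum", "placebo"),
                levels = c("placebo", "verum"))
  graphics::boxplot(arms$log_sd ~ grp, xlab = "", ylab = "log(SD) of time to death",
                    border = "red3", outline = FALSE,
                    ylim = range(arms$log_sd))
  x <- as.numeric(grp) + stats::runif(nrow(arms), -0.05, 0.05)
  graphics::points(x, arms$log_sd, col = "grey40", pch = 16)
  for (id in unique(arms$trial_id)) {
    i <- arms$trial_id == id
    graphics::lines(x[i][order(arms$treatment[i])],
                    arms$log_sd[i][order(arms$treatment[i])], col = "grey70")
  }
  invisible(arms)
}
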