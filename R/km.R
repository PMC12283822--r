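# Kaplan-Meier utilities: rendering step coordinates from individual
# records (the published-figure format), cleaning digitized coordinates,
# and re-estimating curves for round-trip checks.

#' Clean digitized survival-curve coordinates
#'
#' Digitization produces jitter: survival values slightly above 1, below 0,
#' or locally increasing. Cleaning (in order) rescales percent axes to
#' [0, 1] when values exceed 1.5, clips to [0, 1], restores monotone
#' non-increase by pool-adjacent-violators, prepends the anchor point
#' (0, 1) when absent (snapping a jittered time-0 value back to 1), and
#' collapses duplicate times keeping the minimum (post-step) survival.
#' The operation is idempotent on already-clean curves.
#'
#' @param raw Data frame with columns \code{time} and \code{survival}
#'   (column \code{time_months} is accepted as an alias).
#' @return Cleaned curve: data frame with columns \code{time},
#'   \code{survival}, strictly increasing times, first row (0, 1).
#' @export
clean_curve <- function(raw) {
  curve <- assert_curve(raw)
  if (nrow(curve) < 2) stop("curve needs at least 2 points", call. = FALSE)
  curve <- curve[order(curve$time), , drop = FALSE] # stable: keeps step order
  s <- curve$survival
  if (max(s, na.rm = TRUE) > 1.5) s <- s / 100 # percent axis
  s <- pmin(pmax(s, 0), 1)
  s <- pava_nonincreasing(s)
  s <- pmin(pmax(s, 0), 1)
  curve$survival <- s
  if (curve$time[1] > 0) {
    curve <- rbind(data.frame(time = 0, survival = 1), curve)
  } else {
    curve$survival[curve$time == 0] <- 1
  }
  # collapse duplicate times: non-increasing, so min = last occurrence
  keep <- !duplicated(curve$time, fromLast = TRUE)
  curve <- curve[keep, , drop = FALSE]
  rownames(curve) <- NULL
  curve
}

#' Product-limit (Kaplan-Meier) estimate of individual records
#'
#' Returns the step coordinates of the Kaplan-Meier estimator: the anchor
#' (0, 1) plus, at every distinct event time, the pre-step and post-step
#' survival values — the format a digitized published curve arrives in.
#'
#' @param ipd Data frame with columns \code{time}, \code{status}.
#' @return Data frame with columns \code{time}, \code{survival}.
#' @export
km_estimate <- function(ipd) {
  ipd <- assert_ipd(ipd)
  sf <- survival::survfit(survival::Surv(time, status) ~ 1,
                          data = ipd, conf.type = "none")
  ev <- sf$n.event > 0
  et <- sf$time[ev]
  es <- sf$surv[ev]
  tt <- c(0, rep(et, each = 2))
  prev <- c(1, es[-length(es)])
  ss <- c(1, as.vector(rbind(prev, es)))
  data.frame(time = tt, survival = ss)
}

#' Render a simulated arm into published-figure inputs
#'
#' Produces what the reconstruction pipeline consumes for a real trial:
#' the Kaplan-Meier step coordinates and the number-at-risk table at the
#' requested times, plus the total event count.
#'
#' @param ipd Data frame with columns \code{time}, \code{status}.
#' @param risk_times Ordered vector starting at 0 (default: every 6 months
#'   from 0 to the last observed time, the granularity of published
#'   cardiovascular-outcome-trial figures).
#' @return List with elements \code{curve} (data frame \code{time},
#'   \code{survival}), \code{risk} (data frame \code{time},
#'   \code{n_at_risk}) and \code{total_events}.
#' @export
render_km <- function(ipd, risk_times = NULL) {
  ipd <- assert_ipd(ipd)
  if (is.null(risk_times)) {
    risk_times <- seq(0, max(ipd$time) + 6, by = 6)
  }
  if (risk_times[1] != 0 || is.unsorted(risk_times, strictly = TRUE))
    stop("`risk_times` must start at 0 and be strictly increasing", call. = FALSE)
  curve <- km_estimate(ipd)
  risk <- data.frame(
    time = risk_times,
    n_at_risk = vapply(risk_times, function(tt) sum(ipd$time >= tt), integer(1))
  )
  list(curve = curve, risk = risk, total_events = as.integer(sum(ipd$status)))
}

#' Emulate digitization error on a survival curve
#'
#' Adds independent Gaussian noise (pixel-scale, on the survival axis) to
#' every coordinate, then restores the defining properties of a survival
#' curve: the anchor S(0) = 1, monotone non-increase
#' (pool-adjacent-violators) and the range [0, 1].
#'
#' @param curve Data frame with columns \code{time}, \code{survival}.
#' @param noise_sd Standard deviation of the survival-axis noise
#'   (\code{0.005} corresponds to about half a percentage point, a typical
#'   pixel-calibration error).
#' @param seed Integer seed; caller's RNG state is restored.
#' @return Perturbed curve, same shape as the input.
#' @export
perturb_digitization <- function(curve, noise_sd, seed = 1) {
  curve <- assert_curve(curve)
  stopifnot(is.numeric(noise_sd), length(noise_sd) == 1, noise_sd >= 0)
  if (noise_sd == 0) return(curve)
  with_seed(seed, {
    s <- curve$survival + stats::rnorm(nrow(curve), 0, noise_sd)
    s[curve$time == 0] <- 1
    s <- pava_nonincreasing(s)
    curve$survival <- pmin(pmax(s, 0), 1)
    curve
  })
}
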