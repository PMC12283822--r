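# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# Restores the caller's .Random.seed afterwards so library code does not
# clobber user-level reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Round half away from zero (deterministic, unlike IEC 60559 round()).
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Monotone non-increasing least-squares fit (pool-adjacent-violators),
# delegated to stats::isoreg on the negated sequence.
pava_nonincreasing <- function(y) {
  if (length(y) <= 1) return(y)
  -stats::isoreg(seq_along(y), -y)$yf
}

# Coerce/validate an individual-participant-data frame: columns `time`
# (positive) and `status` (0 = censored, 1 = event).
assert_ipd <- function(ipd, allow_empty = FALSE) {
  if (is.matrix(ipd)) ipd <- as.data.frame(ipd)
  if (!is.data.frame(ipd)) stop("`ipd` must be a data frame", call. = FALSE)
  nm <- names(ipd)
  if ("time_months" %in% nm && !"time" %in% nm) names(ipd)[nm == "time_months"] <- "time"
  if (!all(c("time", "status") %in% names(ipd)))
    stop("`ipd` needs columns `time` and `status`", call. = FALSE)
  if (!allow_empty && nrow(ipd) == 0) stop("`ipd` is empty", call. = FALSE)
  if (nrow(ipd) > 0) {
    if (any(!is.finite(ipd$time)) || any(ipd$time <= 0))
      stop("`ipd$time` must be strictly positive and finite", call. = FALSE)
    if (!all(ipd$status %in% c(0, 1)))
      stop("`ipd$status` must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  ipd
}

# Coerce a digitized curve to a two-column data frame (time, survival).
assert_curve <- function(curve) {
  if (is.matrix(curve)) curve <- as.data.frame(curve)
  if (!is.data.frame(curve)) stop("`curve` must be a data frame", call. = FALSE)
  nm <- names(curve)
  if ("time_months" %in% nm && !"time" %in% nm) names(curve)[nm == "time_months"] <- "time"
  if (!all(c("time", "survival") %in% names(curve)))
    stop("`curve` needs columns `time` and `survival`", call. = FALSE)
  if (any(!is.finite(curve$time)) || any(curve$time < 0))
    stop("`curve$time` must be finite and non-negative", call. = FALSE)
  curve[c("time", "survival")]
}

assert_risk_table <- function(risk) {
  if (is.matrix(risk)) risk <- as.data.frame(risk)
  if (!is.data.frame(risk)) stop("`risk` must be a data frame", call. = FALSE)
  nm <- names(risk)
  if ("time_months" %in% nm && !"time" %in% nm) names(risk)[nm == "time_months"] <- "time"
  if (!all(c("time", "n_at_risk") %in% names(risk)))
    stop("`risk` needs columns `time` and `n_at_risk`", call. = FALSE)
  if (nrow(risk) < 1) stop("`risk` is empty", call. = FALSE)
  if (risk$time[1] != 0) stop("risk table must start at time 0", call. = FALSE)
  if (is.unsorted(risk$time, strictly = TRUE))
    stop("risk table times must be strictly increasing", call. = FALSE)
  if (any(risk$n_at_risk < 0) || any(risk$n_at_risk != round(risk$n_at_risk)))
    stop("`n_at_risk` must be non-negative integers", call. = FALSE)
  if (any(diff(risk$n_at_risk) > 0))
    stop("`n_at_risk` must be non-increasing", call. = FALSE)
  risk[c("time", "n_at_risk")]
}
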