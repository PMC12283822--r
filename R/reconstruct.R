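# Reconstruction of individual participant time-to-event records from
# digitized Kaplan-Meier coordinates plus the published number-at-risk
# table: the iterative interval algorithm of Guyot and colleagues,
# preceded by an exact-ratio pass that solves the allocation in closed
# form when the coordinates are numerically exact.
#
# Within each interval between consecutive risk-table times the number of
# censorings is guessed, censoring times are spread uniformly, event
# counts at every digitized step follow from the Kaplan-Meier ratios and
# the running at-risk count, and the guess is iterated until the
# reconstructed number at risk at the next risk-table time matches the
# published value (ties resolved toward fewer censorings).

# Closed-form allocation for numerically exact step coordinates. At every
# event step the Kaplan-Meier ratio 1 - S_k/S_last equals d_k/n_k with
# integer d_k and n_k, so the at-risk count (and hence the censor count in
# every inter-step gap) is identified exactly. Returns NULL whenever the
# implied at-risk counts are not near-integers (digitization noise) or any
# consistency check fails; the caller then falls back to the iterative
# procedure. Ambiguous event counts resolve toward the largest feasible
# d_k, i.e. the fewest censorings.
exact_alloc <- function(tS, S, lower, n_risk, total_events) {
  nt <- length(tS)
  d <- integer(nt)
  cen <- integer(nt)
  n <- n_risk[1]
  lastS <- 1
  bnd <- rep(NA_integer_, nt)
  bnd[lower] <- seq_along(lower)
  for (k in 2:nt) {
    r <- 1 - S[k] / lastS
    had_event <- FALSE
    if (is.finite(r) && r > 1e-12 && lastS > 0) {
      # the 1e-6 guard absorbs float error in n*r = d + c*r just below an
      # integer; it cannot promote a genuine extra event since c*r < 1e-6
      # implies c = 0 at any realistic at-risk count
      dmax <- floor(n * r + 1e-6)
      if (dmax < 1) return(NULL)
      ok <- FALSE
      for (dk in seq.int(dmax, max(1L, dmax - 50L))) {
        n_imp <- dk / r
        if (abs(n_imp - round(n_imp)) < 1e-6 * max(1, n_imp)) {
          n_imp <- round(n_imp)
          cgap <- n - n_imp
          if (cgap >= 0 && n_imp >= dk) { ok <- TRUE; break }
        }
      }
      if (!ok) return(NULL)
      d[k] <- as.integer(dk)
      if (cgap > 0) cen[k - 1L] <- cen[k - 1L] + as.integer(cgap)
      n <- as.integer(n_imp - dk)
      lastS <- S[k]
      had_event <- TRUE
    }
    j <- bnd[k]
    if (!is.na(j) && j > 1L) {
      if (had_event) {
        # event exactly at a risk-table time: the published count must be
        # the pre-event at-risk count, else the closed form is ambiguous
        if (n + d[k] != n_risk[j]) return(NULL)
      } else {
        ctrail <- n - n_risk[j]
        if (ctrail < 0) return(NULL)
        if (ctrail > 0) cen[k - 1L] <- cen[k - 1L] + as.integer(ctrail)
        n <- n_risk[j]
      }
    }
  }
  if (!is.null(total_events) && sum(d) != total_events) return(NULL)
  list(d = d, cen = cen)
}

#' Reconstruct individual participant data from a digitized curve
#'
#' @param curve Digitized step coordinates: data frame with columns
#'   \code{time}, \code{survival}. Cleaned internally via
#'   \code{\link{clean_curve}}; coordinates at the risk-table times are
#'   interpolated from the step function when the digitizer did not click
#'   there.
#' @param risk Number-at-risk table: data frame with columns \code{time}
#'   (starting at 0) and \code{n_at_risk} (non-increasing).
#' @param total_events Optional reported total number of events for the
#'   arm; when supplied, the censoring allocation of the final interval is
#'   adjusted until the reconstructed event count matches it.
#' @return Data frame with columns \code{time} (> 0) and \code{status}
#'   (1 = event at a digitized step time, 0 = censored), one row per
#'   subject, totalling the initial number at risk. Attribute
#'   \code{"detail"} carries the per-click event/censor allocation.
#' @examples
#' ipd <- data.frame(time = c(1, 2, 2.5, 3), status = c(1, 1, 0, 1))
#' r <- render_km(ipd, risk_times = c(0, 4))
#' reconstruct_ipd(r$curve, r$risk, total_events = 3)
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  cv <- clean_curve(curve)
  risk <- assert_risk_table(risk)
  if (!is.null(total_events)) {
    stopifnot(length(total_events) == 1, total_events >= 0,
              total_events == round(total_events))
    total_events <- as.integer(total_events)
  }
  # the digitized curve defines the observed follow-up; risk-table entries
  # beyond its end cannot be localized on the figure and are dropped
  risk <- risk[risk$time <= max(cv$time) + 1e-9, , drop = FALSE]
  n_int <- nrow(risk)
  n_risk <- as.integer(risk$n_at_risk)
  t_risk <- risk$time
  if (n_risk[1] < 1) stop("initial number at risk must be at least 1", call. = FALSE)

  # ensure a coordinate exists at every risk-table time (step
  # interpolation adds no information; it mirrors a digitizer clicking at
  # the grid lines)
  for (rt in t_risk) {
    if (!any(abs(cv$time - rt) <= 1e-9)) {
      j <- max(which(cv$time < rt))
      cv <- rbind(cv, data.frame(time = rt, survival = cv$survival[j]))
    }
  }
  cv <- cv[order(cv$time), , drop = FALSE]
  tS <- cv$time
  S <- cv$survival
  nt <- length(tS)
  lower <- vapply(t_risk, function(rt) which(abs(tS - rt) <= 1e-9)[1], integer(1))
  upper <- c(lower[-1L] - 1L, nt)

  for (i in seq_len(n_int - 1)) {
    if (S[lower[i + 1]] > S[lower[i]] + 1e-12)
      stop(sprintf("reconstruction error in interval %d: survival rises across the interval", i),
           call. = FALSE)
  }

  ex <- exact_alloc(tS, S, lower, n_risk, total_events)
  if (!is.null(ex)) {
    d <- ex$d
    cen <- ex$cen
    KM <- S # closed-form allocation reproduces the curve exactly
    n_cen_interval <- vapply(seq_len(n_int), function(i) {
      gaps <- seq.int(lower[i], if (i < n_int) lower[i + 1] - 1L else nt)
      sum(cen[gaps])
    }, integer(1))
    method <- "exact"
  } else {
    method <- "iterative"

  d <- integer(nt)           # events per click
  cen <- integer(nt)         # censorings per click interval [t_k, t_{k+1})
  n_hat <- integer(nt + 1)   # at risk just before each click
  KM <- rep(1, nt)           # running reconstructed KM estimate
  n_hat[1] <- n_risk[1]
  last_at <- rep(1L, n_int)  # last event click before the start of each interval
  n_cen_interval <- integer(n_int)

  # allocate events/censorings for clicks kfrom..kto given `ncen` censorings
  # spread uniformly on (t_from, t_to); returns updated state
  allocate <- function(kfrom, kto, t_from, t_to, ncen, n_start, last0,
                       d, cen, n_hat, KM) {
    ks <- seq.int(kfrom, kto)
    cen[ks] <- 0L
    if (ncen > 0) {
      cen_t <- t_from + seq_len(ncen) * (t_to - t_from) / (ncen + 1)
      bins <- findInterval(cen_t, tS[seq.int(kfrom, min(kto + 1L, nt))])
      for (b in bins) cen[kfrom + b - 1L] <- cen[kfrom + b - 1L] + 1L
    }
    n_hat[kfrom] <- n_start
    last <- last0
    for (k in ks) {
      if (k == 1L) {
        d[k] <- 0L
        KM[k] <- 1
      } else if (n_hat[k] <= 0L || KM[last] <= 0) {
        d[k] <- 0L
        KM[k] <- KM[last]
      } else {
        dk <- round_half_up(n_hat[k] * (1 - S[k] / KM[last]))
        d[k] <- as.integer(min(max(dk, 0), n_hat[k]))
        KM[k] <- KM[last] * (1 - d[k] / n_hat[k])
      }
      n_hat[k + 1L] <- n_hat[k] - d[k] - cen[k]
      if (n_hat[k + 1L] < 0L) {
        cen[k] <- cen[k] + n_hat[k + 1L]
        if (cen[k] < 0L) { d[k] <- d[k] + cen[k]; cen[k] <- 0L }
        n_hat[k + 1L] <- 0L
      }
      if (d[k] > 0L) last <- k
    }
    list(d = d, cen = cen, n_hat = n_hat, KM = KM, last = last)
  }

  # --- intervals 1 .. n_int-1: iterate censor count to match published risk
  for (i in seq_len(n_int - 1)) {
    kf <- lower[i]; kt <- upper[i]
    denom <- S[lower[i]]
    ncen <- if (denom > 0)
      round_half_up(n_risk[i] * S[lower[i + 1]] / denom) - n_risk[i + 1]
    else 0
    ncen <- max(as.integer(ncen), 0L)
    tried <- integer(0)
    best <- NULL
    repeat {
      if (ncen %in% tried) break
      tried <- c(tried, ncen)
      st <- allocate(kf, kt, tS[kf], t_risk[i + 1], ncen, n_risk[i],
                     last_at[i], d, cen, n_hat, KM)
      mis <- st$n_hat[lower[i + 1]] - n_risk[i + 1]
      if (is.null(best) || abs(mis) < abs(best$mis) ||
          (abs(mis) == abs(best$mis) && ncen < best$ncen)) {
        best <- list(st = st, mis = mis, ncen = ncen)
      }
      if (mis == 0L) break
      if (mis < 0L && ncen == 0L) break # cannot censor fewer than none
      ncen <- min(max(ncen + mis, 0L), n_risk[i]) # bounded so the guard terminates
    }
    st <- best$st
    d <- st$d; cen <- st$cen; n_hat <- st$n_hat; KM <- st$KM
    n_cen_interval[i] <- best$ncen
    if (n_hat[lower[i + 1]] < n_risk[i + 1]) {
      # published at-risk count inconsistent with the curve; carry the
      # reconstructed count forward (digitization noise tolerance)
      n_risk[i + 1] <- n_hat[lower[i + 1]]
    }
    last_at[i + 1] <- st$last
  }

  # --- final interval: extrapolate the average censoring rate
  kf <- lower[n_int]; kt <- upper[n_int]
  run_final <- function(ncen, last0, d, cen, n_hat, KM) {
    allocate(kf, kt, tS[kf], tS[kt], ncen, n_risk[n_int], last0,
             d, cen, n_hat, KM)
  }
  if (n_int > 1) {
    span_prev <- tS[upper[n_int - 1]] - tS[lower[1]]
    ncen_f <- if (span_prev > 0)
      round_half_up(sum(n_cen_interval[seq_len(n_int - 1)]) *
                      (tS[kt] - tS[kf]) / span_prev)
    else 0
    ncen_f <- min(max(as.integer(ncen_f), 0L), n_risk[n_int])
  } else {
    ncen_f <- 0L
  }
  st <- run_final(ncen_f, last_at[n_int], d, cen, n_hat, KM)
  d <- st$d; cen <- st$cen; n_hat <- st$n_hat; KM <- st$KM
  n_cen_interval[n_int] <- ncen_f

  # --- match the reported total event count, if given
  if (!is.null(total_events)) {
    # adjust the last interval that actually contains digitized steps
    adj <- if (kt > kf || n_int == 1) n_int else n_int - 1L
    akf <- lower[adj]
    akt <- if (adj == n_int) upper[n_int] else upper[adj]
    t_to <- if (adj == n_int) tS[akt] else t_risk[adj + 1]
    n_start <- n_risk[adj]
    tried <- integer(0)
    ncen_a <- n_cen_interval[adj]
    repeat {
      sumd <- sum(d)
      if (sumd == total_events) break
      ncen_a <- min(max(ncen_a + (sumd - total_events), 0L), n_risk[adj])
      if (ncen_a %in% tried) break
      tried <- c(tried, ncen_a)
      st <- allocate(akf, akt, tS[akf], t_to, ncen_a, n_start,
                     last_at[adj], d, cen, n_hat, KM)
      if (adj < n_int) {
        # re-run the (degenerate) final interval on the updated state
        st <- run_final(n_cen_interval[n_int], st$last,
                        st$d, st$cen, st$n_hat, st$KM)
      }
      d <- st$d; cen <- st$cen; n_hat <- st$n_hat; KM <- st$KM
      n_cen_interval[adj] <- ncen_a
      if (ncen_a == 0L && sum(d) > total_events) break
    }
    if (sum(d) != total_events)
      warning(sprintf("reconstructed %d events; reported total is %d",
                      sum(d), total_events))
  }
  } # end iterative fallback

  # --- assemble one record per subject
  ev_times <- rep(tS, d)
  cen_times <- numeric(0)
  for (k in which(cen > 0L)) {
    t_hi <- if (k < nt) tS[k + 1L] else max(tS[nt], t_risk[n_int])
    cen_times <- c(cen_times, tS[k] + seq_len(cen[k]) * (t_hi - tS[k]) / (cen[k] + 1))
  }
  n_placed <- length(ev_times) + length(cen_times)
  n_rest <- n_risk[1] - n_placed
  if (n_rest < 0)
    stop("reconstruction error: allocated more records than the initial number at risk",
         call. = FALSE)
  t_end <- max(tS[nt], t_risk[n_int])
  out <- data.frame(
    time = c(ev_times, cen_times, rep(t_end, n_rest)),
    status = c(rep(1L, length(ev_times)), rep(0L, length(cen_times) + n_rest))
  )
  attr(out, "detail") <- list(method = method,
                              clicks = data.frame(time = tS, survival = S,
                                                  events = d, censored = cen),
                              n_censor_interval = n_cen_interval,
                              km_reconstructed = KM)
  out
}
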