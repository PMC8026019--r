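#' Non-compartmental PK metrics
#'
#' Model-free summaries of concentration-time curves: AUC by the linear
#' trapezoid, Cmax/Tmax, terminal half-life by best-fit log-linear regression,
#' and multi-dose steady-state metrics. These operate identically on observed
#' sparse curves and on dense simulated trajectories.
#'
#' @name pk_metrics
NULL

#' Area under the concentration-time curve
#'
#' Linear trapezoidal integral over `[time[1], t_end]`, with linear
#' interpolation at `t_end` when it falls between grid points. On the dense
#' default simulation grid the method choice (linear vs log-down) changes the
#' result by far less than 0.1%, so the simple trapezoid is used throughout.
#'
#' @param time sorted time vector, h
#' @param conc concentrations, nmol/mL
#' @param t_end upper integration limit, h (defaults to the last time;
#'   must not exceed it)
#' @return AUC, nmol*h/mL
#' @export
auc <- function(time, conc, t_end = max(time)) {
  if (length(time) < 2) stop("AUC needs at least 2 points", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing", call. = FALSE)
  if (t_end > max(time) + 1e-9) stop("t_end beyond the observed window", call. = FALSE)
  keep <- time <= t_end
  tt <- time[keep]; cc <- conc[keep]
  if (t_end > max(tt)) { # interpolate the end point
    ci <- stats::approx(time, conc, xout = t_end)$y
    tt <- c(tt, t_end); cc <- c(cc, ci)
  }
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Maximum concentration and its time
#'
#' Global maximum of the curve; ties are broken by the earliest time. With
#' `interpolate = TRUE` (for dense simulated curves) the peak is refined by a
#' quadratic fit through the three points around the grid maximum, giving
#' sub-grid Tmax resolution.
#'
#' @param time time vector, h
#' @param conc concentrations, nmol/mL
#' @param interpolate refine the peak parabolically (default off, exact for
#'   observed data)
#' @return list with `cmax` (nmol/mL) and `tmax` (h)
#' @export
cmax_tmax <- function(time, conc, interpolate = FALSE) {
  if (!length(time)) stop("empty series", call. = FALSE)
  i <- which.max(conc) # which.max returns the first (earliest) maximum
  cmax <- conc[i]; tmax <- time[i]
  if (interpolate && i > 1 && i < length(conc)) {
    t3 <- time[(i - 1):(i + 1)]; c3 <- conc[(i - 1):(i + 1)]
    d1 <- (c3[3] - c3[1]) / (t3[3] - t3[1])
    d2 <- ((c3[3] - c3[2]) / (t3[3] - t3[2]) - (c3[2] - c3[1]) / (t3[2] - t3[1])) /
      ((t3[3] - t3[1]) / 2)
    if (d2 < 0) {
      tv <- t3[2] - d1 / d2
      if (tv >= t3[1] && tv <= t3[3]) {
        tmax <- tv
        cmax <- c3[2] + d1 * (tv - t3[2]) - d2 / 2 * (tv - t3[2])^2
        cmax <- max(cmax, c3[2])
      }
    }
  }
  list(cmax = cmax, tmax = tmax)
}

# Suffix log-linear regressions, vectorized via reverse cumulative sums:
# returns slope and adjusted R^2 for every suffix window of >= min_points.
suffix_loglin <- function(tt, ly, min_points) {
  n <- length(tt)
  rc <- function(x) rev(cumsum(rev(x)))
  k <- n - seq_len(n) + 1 # window size for suffix starting at i
  sx <- rc(tt); sy <- rc(ly); sxx <- rc(tt^2); syy <- rc(ly^2); sxy <- rc(tt * ly)
  vx <- sxx - sx^2 / k
  vy <- syy - sy^2 / k
  cxy <- sxy - sx * sy / k
  slope <- cxy / vx
  r2 <- cxy^2 / (vx * vy)
  adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
  ok <- k >= max(3, min_points) & vx > 0 & vy > 0
  list(start = seq_len(n), slope = slope, adj_r2 = adj, ok = ok, n = k)
}

#' Terminal half-life (lambda-z)
#'
#' `ln(2) / lambda_z`, where `lambda_z` is the negative slope of log
#' concentration versus time over the terminal window. The window is chosen
#' by maximizing the adjusted R-squared over all suffixes of at least
#' `min_points` points strictly after Tmax (the usual NCA best-fit
#' convention). Non-positive concentrations are excluded from the regression.
#'
#' @param time time vector, h
#' @param conc concentrations, nmol/mL
#' @param min_points minimum terminal window size (default 3)
#' @return half-life, h
#' @export
terminal_half_life <- function(time, conc, min_points = 3) {
  i_max <- which.max(conc)
  sel <- seq_along(time) > i_max & conc > 0
  tt <- time[sel]; cc <- conc[sel]
  if (length(tt) < max(3, min_points)) {
    stop("need at least 3 positive points after Tmax", call. = FALSE)
  }
  s <- suffix_loglin(tt, log(cc), min_points)
  cand <- which(s$ok & s$slope < 0)
  if (!length(cand)) stop("undefined half-life: no negative terminal slope", call. = FALSE)
  best <- cand[which.max(s$adj_r2[cand])]
  log(2) / -s$slope[best]
}

#' Single-dose PK summary for one compartment
#'
#' AUC to `t_auc`, Cmax/Tmax (parabolically refined on the dense grid),
#' terminal half-life, and the amount of drug in the compartment at Tmax
#' (concentration times volume, reported in mg free base).
#'
#' @param result a `pbpk_sim`
#' @param compartment compartment name
#' @param t_auc AUC integration limit, h (default 24)
#' @return one-row data.frame
#' @export
pk_summary <- function(result, compartment, t_auc = 24) {
  pr <- sim_conc(result, compartment)
  pk <- cmax_tmax(pr$time, pr$conc, interpolate = TRUE)
  vol <- result$model$compartments$volume[result$model$compartments$name == compartment]
  th <- tryCatch(terminal_half_life(pr$time, pr$conc), error = function(e) NA_real_)
  data.frame(
    compartment = compartment,
    auc = auc(pr$time, pr$conc, min(t_auc, max(pr$time))),
    cmax = pk$cmax, tmax = pk$tmax,
    amount_at_cmax_mg = nmol_to_mg(pk$cmax * vol),
    t_half = th,
    stringsAsFactors = FALSE)
}

#' Multi-dose PK summary for one compartment
#'
#' Cmax and Tmax over the whole course (a single value per regimen, so for an
#' accumulating regimen Tmax can fall in a late interval), average
#' steady-state concentration `Cmean = AUC(last complete interval) / tau`,
#' AUC over the first 24 h, and the terminal half-life after the final dose.
#' A `steady_state` flag records whether the per-interval peak converged
#' (see [steady_state_time()]); when it did not, `Cmean` still refers to the
#' last simulated interval and the flag is the warning.
#'
#' @param result a `pbpk_sim` covering at least two dosing intervals
#' @param compartment compartment name
#' @param tau dosing interval, h
#' @param dose_times dose times (defaults to the stored schedule)
#' @return one-row data.frame
#' @export
multidose_summary <- function(result, compartment, tau,
                              dose_times = result$schedule$time) {
  if (length(dose_times) < 2) stop("multi-dose summary needs >= 2 doses", call. = FALSE)
  pr <- sim_conc(result, compartment)
  pk <- cmax_tmax(pr$time, pr$conc, interpolate = TRUE)
  last_start <- max(dose_times)
  last_end <- last_start + tau
  if (max(pr$time) < last_end) stop("simulation too short for the final interval", call. = FALSE)
  sel <- pr$time >= last_start & pr$time <= last_end
  cmean <- auc(pr$time[sel], pr$conc[sel]) / tau
  sst <- steady_state_time(result, compartment, tau, dose_times)
  tail_sel <- pr$time >= last_start
  th <- tryCatch(terminal_half_life(pr$time[tail_sel], pr$conc[tail_sel]),
                 error = function(e) NA_real_)
  vol <- result$model$compartments$volume[result$model$compartments$name == compartment]
  data.frame(
    compartment = compartment,
    auc24 = auc(pr$time, pr$conc, min(24, max(pr$time))),
    cmax = pk$cmax, cmean = cmean,
    amount_at_cmax_mg = nmol_to_mg(pk$cmax * vol),
    tmax = pk$tmax, t_half = th,
    steady_state = is.finite(sst$time), steady_state_h = sst$time,
    stringsAsFactors = FALSE)
}

#' Time to steady state under repeated dosing
#'
#' Splits the course into complete dosing intervals and finds the first
#' interval whose peak concentration differs from the previous interval's by
#' less than `tolerance` (relative); the start of that interval is the time
#' steady state is reached. For a compartment that is still accumulating when
#' dosing stops (its global maximum falls after the last dose), the time of
#' the global maximum is returned instead. If neither applies the time is
#' `NA` with `reached = FALSE`.
#'
#' @param result a `pbpk_sim`
#' @param compartment compartment name
#' @param tau dosing interval, h
#' @param dose_times dose times (defaults to the stored schedule)
#' @param tolerance relative change in per-interval Cmax (default 0.01)
#' @return list with `time` (h, possibly `NA`) and `reached` (logical)
#' @export
steady_state_time <- function(result, compartment, tau,
                              dose_times = result$schedule$time,
                              tolerance = 0.01) {
  if (length(dose_times) < 2) {
    return(list(time = NA_real_, reached = FALSE))
  }
  pr <- sim_conc(result, compartment)
  starts <- dose_times
  peaks <- vapply(starts, function(t0) {
    sel <- pr$time >= t0 & pr$time <= t0 + tau
    if (!any(sel)) NA_real_ else max(pr$conc[sel])
  }, 0)
  rel <- abs(diff(peaks)) / utils::head(peaks, -1)
  hit <- which(rel < tolerance)
  if (length(hit)) return(list(time = starts[hit[1] + 1], reached = TRUE))
  # never converged during dosing; if the global peak falls beyond the last
  # dose the compartment was still accumulating: report the peak time
  glob <- cmax_tmax(pr$time, pr$conc, interpolate = TRUE)
  if (glob$tmax > max(dose_times)) {
    return(list(time = glob$tmax, reached = TRUE))
  }
  list(time = NA_real_, reached = FALSE)
}

#' Oscillation amplitude and mean at steady state
#'
#' Peak-to-trough amplitude (`Cmax - Cmin`) and time-average concentration of
#' the final complete dosing interval. Errors if steady state was never
#' reached (per [steady_state_time()]).
#'
#' @inheritParams multidose_summary
#' @return list with `amplitude` and `mean` (nmol/mL)
#' @export
oscillation_metrics <- function(result, compartment, tau,
                                dose_times = result$schedule$time) {
  sst <- steady_state_time(result, compartment, tau, dose_times)
  if (!sst$reached) {
    stop(sprintf("'%s' did not reach steady state within the simulation", compartment),
         call. = FALSE)
  }
  pr <- sim_conc(result, compartment)
  t0 <- max(dose_times)
  sel <- pr$time >= t0 & pr$time <= t0 + tau
  list(amplitude = max(pr$conc[sel]) - min(pr$conc[sel]),
       mean = auc(pr$time[sel], pr$conc[sel]) / tau)
}

#' Amount-based distribution metrics
#'
#' Per-tissue amount curves in mg free base (concentration times volume) and
#' each tissue's peak amount as a fraction of the absorbed dose. The absorbed
#' amount is taken as the cumulative urinary excretion at the end of a long
#' single-dose run, since all absorbed drug is ultimately excreted renally.
#'
#' @param result a `pbpk_sim` of a single-dose run long enough for urinary
#'   excretion to be essentially complete
#' @return list with `absorbed_mg`, `amounts_mg` (time x compartment matrix)
#'   and `peak_fraction` (named vector, peak amount / absorbed)
#' @export
amount_metrics <- function(result) {
  absorbed <- utils::tail(result$amounts[, "urine"], 1)
  comp <- result$model$compartments
  keep <- comp$kind != "excreta"
  amounts_mg <- nmol_to_mg(result$amounts[, comp$name[keep], drop = FALSE])
  peaks <- apply(amounts_mg, 2, max)
  list(absorbed_mg = nmol_to_mg(absorbed),
       amounts_mg = amounts_mg,
       peak_fraction = peaks / nmol_to_mg(absorbed))
}

#' Dose-regimen summary table for all tissues
#'
#' One summary row per reported tissue, mirroring the usual publication
#' layout (tissue, dose, AUC24, Cmax, [Cmean], amount at Cmax, Tmax, T1/2).
#' The AUC column is always the 0-24 h integral and is labelled as such.
#'
#' @param result a `pbpk_sim`
#' @param dose_mg_hcl dose label, mg metformin hydrochloride
#' @param tau dosing interval for multi-dose regimens; `NULL` for single dose
#' @param compartments compartments to report (default: the measurable
#'   tissues and fluids)
#' @return data.frame
#' @export
pk_summary_table <- function(result, dose_mg_hcl, tau = NULL,
                             compartments = NULL) {
  if (is.null(compartments)) {
    compartments <- intersect(
      c("venous_plasma", "rbc", "adipose", "brain", "remainder", "muscle",
        "enterocytes", "lungs", "stomach", "heart", "liver", "kidney_tissue"),
      colnames(result$conc))
  }
  rows <- lapply(compartments, function(cp) {
    if (is.null(tau)) {
      s <- pk_summary(result, cp)
      data.frame(tissue = cp, dose_mg_hcl = dose_mg_hcl, auc24 = s$auc,
                 cmax = s$cmax, cmean = NA_real_,
                 amount_at_cmax_mg = s$amount_at_cmax_mg,
                 tmax = s$tmax, t_half = s$t_half, stringsAsFactors = FALSE)
    } else {
      s <- multidose_summary(result, cp, tau)
      data.frame(tissue = cp, dose_mg_hcl = dose_mg_hcl, auc24 = s$auc24,
                 cmax = s$cmax, cmean = s$cmean,
                 amount_at_cmax_mg = s$amount_at_cmax_mg,
                 tmax = s$tmax, t_half = s$t_half, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
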