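#' Map of observation-channel positions to reaction times
#'
#' In the droplet-based mixer, reaction time is set by the measurement
#' position along the observation channel and the droplet velocity
#' (~0.6 mm/s), giving access to times from milliseconds to ~60 s over a
#' 36 mm channel.
#'
#' @param positions Measurement positions along the channel, mm.
#' @param droplet_velocity Droplet velocity, mm/s.
#' @param dead_time Time offset (s) before the first observation point
#'   (e.g. mixing dead time).
#' @return Object of class `timepoint_map`.
#' @export
timepoint_map <- function(positions = numeric(), droplet_velocity = 0.6,
                          dead_time = 0) {
  stopifnot(droplet_velocity > 0, dead_time >= 0, all(positions >= 0))
  times <- dead_time + positions / droplet_velocity
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("positions must give strictly increasing times")
  structure(list(positions = positions,
                 droplet_velocity = droplet_velocity,
                 dead_time = dead_time, times = times),
            class = "timepoint_map")
}

#' Convert a channel position to reaction time
#'
#' @param map A [timepoint_map()].
#' @param position Position along the observation channel, mm (>= 0).
#' @return Reaction time `dead_time + position / velocity`, s.
#' @export
#' @examples
#' position_to_time(timepoint_map(), 36) # 60 s at 0.6 mm/s
position_to_time <- function(map, position) {
  stopifnot(inherits(map, "timepoint_map"))
  if (any(position < 0)) stop("position must be >= 0")
  map$dead_time + position / map$droplet_velocity
}

#' Two-state pseudo-first-order relaxation
#'
#' The decompacted fraction under a two-state model with one reactant in
#' large excess (pseudo-first-order conditions) relaxes as a single
#' exponential: `f(t) = f_inf - (f_inf - f0) * exp(-k_obs * t)`.
#'
#' @param t Reaction times, s (>= 0).
#' @param k_obs Observed rate, 1/s.
#' @param f0 Fraction at t = 0.
#' @param f_inf Equilibrium fraction.
#' @return Fractions at `t`.
#' @export
#' @examples
#' two_state_fraction(1 / 0.42, 0.42, 0, 1) # 1 - exp(-1)
two_state_fraction <- function(t, k_obs, f0, f_inf) {
  stopifnot(all(t >= 0), k_obs >= 0)
  f_inf - (f_inf - f0) * exp(-k_obs * t)
}

#' Fit two-state pseudo-first-order kinetics
#'
#' Weighted nonlinear least squares of [two_state_fraction()] to a series
#' of decompacted fractions versus reaction time, with bounds
#' `k_obs >= 0` and fractions in \[0, 1\]. Weights are inverse fraction
#' uncertainties (a small floor guards against zero uncertainties from
#' saturated histograms). Confidence intervals are t-based from the
#' covariance of the weighted fit.
#'
#' @param times Reaction times, s (>= 4 points).
#' @param f_dec Decompacted fraction per time point.
#' @param se Fraction uncertainties (optional; equal weights if missing).
#' @param conf_level Confidence level for the intervals.
#' @param condition Optional named list of condition metadata (e.g. PAR
#'   length, PAR chain concentration in nM, ionic strength in mM),
#'   attached to the result for [summarize_conditions()].
#' @return Object of class `kinetic_fit`: estimates (`k_obs`, `f0`,
#'   `f_inf`), standard errors, confidence intervals, covariance,
#'   residual diagnostics, and a `flat` flag (set, with `k_obs = 0`, when
#'   the series carries no resolvable time dependence).
#' @export
#' @examples
#' t <- c(0.05, 0.2, 1, 3, 10)
#' f <- two_state_fraction(t, 0.42, 0.1, 0.9)
#' fit_kinetics(t, f)
fit_kinetics <- function(times, f_dec, se = NULL, conf_level = 0.95,
                         condition = NULL) {
  stopifnot(length(times) == length(f_dec), all(times >= 0))
  ok <- is.finite(times) & is.finite(f_dec)
  times <- times[ok]; f_dec <- f_dec[ok]
  if (!is.null(se)) se <- se[ok]
  if (length(times) < 4) stop("need at least 4 time points")
  if (is.null(se)) se <- rep(1, length(times))
  se <- pmax(se, 0.005)
  o <- order(times)
  times <- times[o]; f_dec <- f_dec[o]; se <- se[o]
  flat <- stats::sd(f_dec) < 1e-12
  if (flat) {
    est <- c(k_obs = 0, f0 = mean(f_dec), f_inf = mean(f_dec))
    out <- list(estimate = est,
                se = c(k_obs = NA, f0 = NA, f_inf = NA), ci = NULL,
                cov = NULL, flat = TRUE, condition = condition,
                times = times, f_dec = f_dec, weights_se = se)
    class(out) <- "kinetic_fit"
    return(out)
  }
  f0_init <- f_dec[1]
  finf_init <- f_dec[length(f_dec)]
  # crude rate guess: time at which half the total change has occurred
  half <- (f0_init + finf_init) / 2
  t_half <- times[which.min(abs(f_dec - half))]
  k_init <- log(2) / max(t_half, min(times[times > 0], 1e-3))
  resid_fun <- function(p)
    (two_state_fraction(times, p[1], p[2], p[3]) - f_dec) / se
  fit <- minpack.lm::nls.lm(
    par = c(k_init, min(max(f0_init, 0), 1), min(max(finf_init, 0), 1)),
    lower = c(0, 0, 0), upper = c(Inf, 1, 1), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 20000,
                                         ftol = 1e-13, ptol = 1e-13))
  if (!fit$info %in% 1:4)
    stop("kinetic fit did not converge: ", fit$message)
  p <- fit$par
  names(p) <- c("k_obs", "f0", "f_inf")
  vc <- fit_covariance(resid_fun, p, length(times))
  dimnames(vc) <- list(names(p), names(p))
  pse <- sqrt(pmax(diag(vc), 0))
  df <- max(1, length(times) - 3)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  ci <- cbind(lower = p - tq * pse, upper = p + tq * pse)
  ci["k_obs", "lower"] <- max(0, ci["k_obs", "lower"])
  out <- list(estimate = p, se = pse, ci = ci, cov = vc,
              conf_level = conf_level, flat = FALSE,
              condition = condition, times = times, f_dec = f_dec,
              weights_se = se, deviance = fit$deviance, info = fit$info)
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$flat) {
    cat(sprintf("kinetic fit: flat series, k_obs = 0 (f = %.3g)\n",
                x$estimate[["f0"]]))
    return(invisible(x))
  }
  cat(sprintf("two-state fit: k_obs = %.4g +/- %.2g /s, f0 = %.3g, f_inf = %.3g\n",
              x$estimate[["k_obs"]], x$se[["k_obs"]],
              x$estimate[["f0"]], x$estimate[["f_inf"]]))
  cat(sprintf("  %d%% CI on k_obs: [%.4g, %.4g]\n",
              round(100 * x$conf_level), x$ci["k_obs", "lower"],
              x$ci["k_obs", "upper"]))
  invisible(x)
}

#' Segment a slow trace into fixed windows
#'
#' Splits a long manual-mixing photon stream into consecutive
#' non-overlapping windows (one minute by default, each containing ~1000
#' bursts at typical rates) and runs the slow-mode burst search on each.
#' The window midpoint serves as the reaction-time coordinate. A final
#' partial window is dropped with a message.
#'
#' @param stream A [photon_stream()] covering at least one window.
#' @param window Window length, s.
#' @param params Burst-search settings (slow mode by default).
#' @param instrument An [instrument_spec()].
#' @return List with `midpoints` (s, relative to the stream start) and
#'   `bursts` (list of `burst_table`, one per window).
#' @export
segment_trace <- function(stream, window = 60,
                          params = burst_search_params("slow"),
                          instrument = instrument_spec()) {
  stopifnot(inherits(stream, "photon_stream"), window > 0)
  t <- photon_times(stream)
  span <- if (length(t)) max(t) else 0
  n_win <- floor(span / window)
  # a trailing window covered to >= 99% counts as complete (the recording
  # nominally spans it; only the last burst's exact arrival differs)
  if (span - n_win * window >= 0.99 * window) n_win <- n_win + 1
  if (n_win < 1) stop("stream shorter than one window")
  if (span - n_win * window > 0)
    message(sprintf("dropping final partial window (%.3g s)",
                    span - n_win * window))
  idx <- findInterval(t, seq(0, n_win * window, by = window),
                      rightmost.closed = FALSE)
  bursts <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    sel <- idx == k
    sub <- photon_stream(stream$ticks[sel], stream$channel[sel],
                         stream$microtime_ns[sel],
                         clock_rate_hz = attr(stream, "clock_rate_hz"))
    bursts[[k]] <- find_bursts(sub, params, instrument)
  }
  list(midpoints = (seq_len(n_win) - 0.5) * window, bursts = bursts)
}

#' Tabulate kinetic fits across experimental conditions
#'
#' Collects per-condition two-state fits into a long-format table of
#' observed rates and equilibrium decompacted fractions. No interpolation
#' or modelling across conditions is performed.
#'
#' @param fits List of `kinetic_fit` objects carrying `condition`
#'   metadata (any of `par_length`, `par_conc_nM`, `ionic_strength_mM`).
#' @return Data frame with one row per fit: condition columns, `k_obs`,
#'   `k_obs_se`, `f_inf`, `f_inf_se`.
#' @export
summarize_conditions <- function(fits) {
  cols <- c("par_length", "par_conc_nM", "ionic_strength_mM")
  if (!length(fits))
    return(data.frame(par_length = character(), par_conc_nM = numeric(),
                      ionic_strength_mM = numeric(), k_obs = numeric(),
                      k_obs_se = numeric(), f_inf = numeric(),
                      f_inf_se = numeric()))
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "kinetic_fit"))
    cond <- f$condition
    row <- data.frame(
      par_length = if (is.null(cond$par_length)) NA else cond$par_length,
      par_conc_nM = if (is.null(cond$par_conc_nM)) NA_real_ else
        cond$par_conc_nM,
      ionic_strength_mM = if (is.null(cond$ionic_strength_mM)) NA_real_
        else cond$ionic_strength_mM,
      k_obs = f$estimate[["k_obs"]],
      k_obs_se = f$se[["k_obs"]],
      f_inf = f$estimate[["f_inf"]],
      f_inf_se = f$se[["f_inf"]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
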