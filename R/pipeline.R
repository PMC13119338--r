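#' Run the droplet-mode analysis pipeline on a kinetic series
#'
#' Full analysis chain for a droplet-mixer kinetic series: burst search
#' (fast mode) on each time point's photon stream, PIE corrections to
#' per-burst (E, S), stoichiometry gating, transfer-efficiency histograms,
#' global two-Gaussian fit with shared peak positions and shot-noise
#' widths, and a two-state pseudo-first-order fit of the decompacted
#' fraction versus time. Elements of `streams` may alternatively be
#' `burst_table`s (e.g. from the counts-level generator path), in which
#' case burst search is skipped.
#'
#' @param streams List of [photon_stream()]s or `burst_table`s, one per
#'   time point.
#' @param times Reaction times (s), same length as `streams`.
#' @param instrument An [instrument_spec()].
#' @param corr A [correction_set()]; defaults to the set matching
#'   `instrument`.
#' @param params Burst-search settings (fast mode default).
#' @param gate Stoichiometry gate `c(s_low, s_high)`.
#' @param bin_width,range Histogram settings.
#' @param min_bursts Expected bursts per time point for [burst_qc()].
#' @param condition Optional condition metadata for the kinetic fit.
#' @return List of class `droplet_analysis`: `bursts`, `points`, `hists`,
#'   `hist_fit`, `fractions` (data frame with `time`, `f_dec`, `se`), and
#'   `kinetic_fit`.
#' @export
analyze_droplet_series <- function(streams, times,
                                   instrument = instrument_spec(),
                                   corr = correction_set_from_instrument(instrument),
                                   params = burst_search_params("fast"),
                                   gate = c(0.2, 0.8),
                                   bin_width = 0.025, range = c(-0.1, 1.1),
                                   min_bursts = 3000, condition = NULL) {
  stopifnot(length(streams) == length(times))
  bursts <- lapply(streams, function(s) {
    if (inherits(s, "photon_stream")) find_bursts(s, params, instrument)
    else s
  })
  bursts <- lapply(bursts, function(b)
    suppressWarnings(burst_qc(b, min_bursts)))
  points <- lapply(bursts, fret_points, corr = corr)
  gated <- lapply(points, gate_stoichiometry, s_low = gate[1],
                  s_high = gate[2])
  hist_fit <- fit_population_histograms(gated, times, corr, peaks = 2,
                                        bin_width = bin_width,
                                        range = range)
  hists <- attr(hist_fit, "histograms")
  fr <- hist_fit$fractions
  fractions <- data.frame(time = times,
                          f_dec = 1 - fr$fraction_compact, se = fr$se)
  kin <- fit_kinetics(fractions$time, fractions$f_dec, fractions$se,
                      condition = condition)
  structure(list(bursts = bursts, points = gated, hists = hists,
                 hist_fit = hist_fit, fractions = fractions,
                 kinetic_fit = kin),
            class = "droplet_analysis")
}

#' @export
print.droplet_analysis <- function(x, ...) {
  cat(sprintf("droplet-mode analysis: %d time points, %d gated bursts\n",
              nrow(x$fractions), sum(vapply(x$points, nrow, integer(1)))))
  print(x$hist_fit)
  print(x$kinetic_fit)
  invisible(x)
}

#' Fit efficiency histograms of gated FRET points with pipeline defaults
#'
#' Convenience wrapper around [fit_efficiency_histograms()] used by the
#' analysis pipelines: pools the gated points to determine the reference
#' photon count (harmonic mean, see [n_ref_photons()]), constrains peak
#' widths to the correction-propagated counting noise
#' ([shot_noise_sigma_corrected()]), builds one histogram per element of
#' `points`, and runs the global fit.
#'
#' @param points A `fret_points` data frame (already gated) or list of
#'   them, one per time point.
#' @param times Timepoint labels, same length as `points` (optional).
#' @param corr The [correction_set()] the points were computed with.
#' @param peaks Number of Gaussian peaks.
#' @param bin_width,range Histogram settings.
#' @return A `fret_hist_fit` (with the histograms attached as attribute
#'   `histograms`).
#' @export
fit_population_histograms <- function(points, times = NULL, corr,
                                      peaks = 2, bin_width = 0.025,
                                      range = c(-0.1, 1.1)) {
  if (is.data.frame(points)) points <- list(points)
  if (is.null(times)) times <- seq_along(points)
  stopifnot(length(points) == length(times))
  pooled <- do.call(rbind, points)
  n_ref <- n_ref_photons(pooled)
  a_ref <- stats::median(pooled$F_AA)
  d_ref <- stats::median(pooled$duration)
  sigma_fun <- function(mu)
    shot_noise_sigma_corrected(mu, n_ref, corr, A_ref = a_ref,
                               d_ref = d_ref)
  hists <- lapply(seq_along(points), function(i)
    efficiency_histogram(points[[i]]$E, bin_width = bin_width,
                         range = range, timepoint = times[i]))
  fit <- fit_efficiency_histograms(hists, n_ref = n_ref, peaks = peaks,
                                   sigma_fun = sigma_fun)
  attr(fit, "histograms") <- hists
  fit
}

#' Run the slow manual-mixing analysis pipeline on a single trace
#'
#' Segments a long photon trace into fixed windows (one minute by
#' default), runs the slow-mode burst search (60 photons per 1-ms bin) in
#' each, and proceeds as in [analyze_droplet_series()] with the window
#' midpoints (plus the manual-mixing dead time) as reaction times.
#'
#' @param stream A [photon_stream()] of the full recording.
#' @param instrument,corr,gate,bin_width,range,condition As in
#'   [analyze_droplet_series()].
#' @param window Segmentation window, s.
#' @param dead_time Reaction time at the start of the recording, s
#'   (manual mixing takes ~5 s).
#' @param params Burst-search settings (slow mode default).
#' @param min_bursts Expected bursts per window.
#' @return A `droplet_analysis`-style list (same components).
#' @export
analyze_slow_trace <- function(stream, instrument = instrument_spec(),
                               corr = correction_set_from_instrument(instrument),
                               window = 60, dead_time = 5,
                               params = burst_search_params("slow"),
                               gate = c(0.2, 0.8),
                               bin_width = 0.025, range = c(-0.1, 1.1),
                               min_bursts = 1000, condition = NULL) {
  seg <- segment_trace(stream, window = window, params = params,
                       instrument = instrument)
  analyze_droplet_series(seg$bursts, dead_time + seg$midpoints,
                         instrument = instrument, corr = corr,
                         params = params, gate = gate,
                         bin_width = bin_width, range = range,
                         min_bursts = min_bursts, condition = condition)
}
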