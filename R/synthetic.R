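#' Expected per-burst photon counts for a species
#'
#' Computes the expected detected counts per burst in the three
#' channel/excitation-window classes used by the analysis: `DD` (donor
#' channel, donor excitation), `DA` (acceptor channel, donor excitation)
#' and `AA` (acceptor channel, acceptor excitation). The expectations are
#' the exact inverse of the correction chain applied by [correct_counts()]:
#'
#' * signal `sig_DD = (1 - E) * B_D / gamma`, `sig_DA = E * B_D`,
#'   `sig_AA = B_A`, where `B_D` is the gamma-weighted donor-excitation
#'   brightness and `B_A` the acceptor-excitation brightness;
#' * raw `DA` expectation adds leakage `alpha * sig_DD`, direct excitation
#'   `delta * sig_AA` and background; `DD`/`AA` add only background.
#'
#' Donor-only species carry no acceptor signal beyond background;
#' acceptor-only species no donor-excitation signal beyond background.
#'
#' @param species A [species_spec()].
#' @param instrument An [instrument_spec()].
#' @param intensity Relative burst intensity (1 = species mean brightness).
#' @return List with `signal` and `raw` named vectors (`DD`, `DA`, `AA`,
#'   `AD`) of expected counts per burst of duration
#'   `instrument$mean_burst_duration`.
#' @export
#' @examples
#' sp <- species_spec("compact", true_E = 0.36, brightness_D_ex = 100)
#' burst_count_expectations(sp, instrument_spec(gamma = 1.2))$raw
burst_count_expectations <- function(species, instrument, intensity = 1) {
  stopifnot(inherits(species, "species_spec"),
            inherits(instrument, "instrument_spec"),
            intensity >= 0)
  E <- species$true_E
  g <- instrument$gamma
  BD <- species$brightness_D_ex * intensity
  BA <- species$brightness_A_ex * intensity
  sig <- switch(species$labeled_state,
    "double"        = c(DD = (1 - E) * BD / g, DA = E * BD, AA = BA),
    "donor-only"    = c(DD = BD / g,           DA = 0,      AA = 0),
    "acceptor-only" = c(DD = 0,                DA = 0,      AA = BA))
  bg <- background_window_rates(instrument) * instrument$mean_burst_duration
  raw <- c(
    DD = sig[["DD"]] + bg[["DD"]],
    DA = sig[["DA"]] + instrument$leakage_alpha * sig[["DD"]] +
      instrument$direct_excitation_delta * sig[["AA"]] + bg[["DA"]],
    AA = sig[["AA"]] + bg[["AA"]],
    AD = bg[["AD"]])
  if (!all(is.finite(raw)) || any(raw < 0))
    stop("non-finite or negative expected counts")
  list(signal = c(sig, AD = 0), raw = raw)
}

# Background rates (photons/s) per channel-window class. Background photons
# arrive uniformly over the PIE period, so each detection channel's rate is
# split between the two excitation windows in proportion to window length.
background_window_rates <- function(instrument) {
  f_Dex <- (instrument$pie_period - instrument$microtime_split) /
    instrument$pie_period
  f_Aex <- 1 - f_Dex
  c(DD = instrument$background_rates[["D"]] * f_Dex,
    DA = instrument$background_rates[["A"]] * f_Dex,
    AA = instrument$background_rates[["A"]] * f_Aex,
    AD = instrument$background_rates[["D"]] * f_Aex)
}

# Vectorised counts-level burst simulation. `species` is a list of
# species_spec, `species_id` an integer index per burst. Burst-to-burst
# intensity varies lognormally (sdlog) with mean 1, mimicking the broad
# burst-size distribution from diffusion through the confocal volume.
# With include_background = TRUE the counts include background accumulated
# over mean_burst_duration (counts-only fast path); the photon-level path
# lays background down along the stream instead.
simulate_burst_counts <- function(species, species_id, instrument,
                                  size_sdlog = 0.45,
                                  include_background = TRUE) {
  n <- length(species_id)
  stopifnot(all(species_id >= 1), all(species_id <= length(species)))
  u <- stats::rlnorm(n, meanlog = -size_sdlog^2 / 2, sdlog = size_sdlog)
  g <- instrument$gamma
  BD <- vapply(species, `[[`, numeric(1), "brightness_D_ex")[species_id] * u
  BA <- vapply(species, `[[`, numeric(1), "brightness_A_ex")[species_id] * u
  E  <- vapply(species, `[[`, numeric(1), "true_E")[species_id]
  state <- vapply(species, `[[`, character(1), "labeled_state")[species_id]
  sDD <- sDA <- sAA <- numeric(n)
  dbl <- state == "double"; don <- state == "donor-only"
  acc <- state == "acceptor-only"
  sDD[dbl] <- (1 - E[dbl]) * BD[dbl] / g
  sDA[dbl] <- E[dbl] * BD[dbl]
  sAA[dbl] <- BA[dbl]
  sDD[don] <- BD[don] / g
  sAA[acc] <- BA[acc]
  lamDA <- sDA + instrument$leakage_alpha * sDD +
    instrument$direct_excitation_delta * sAA
  d <- instrument$mean_burst_duration
  bg <- if (include_background) background_window_rates(instrument) * d else
    c(DD = 0, DA = 0, AA = 0, AD = 0)
  out <- data.frame(
    species = vapply(species, `[[`, character(1), "name")[species_id],
    duration = d,
    n_DD = stats::rpois(n, sDD + bg[["DD"]]),
    n_DA = stats::rpois(n, lamDA + bg[["DA"]]),
    n_AA = stats::rpois(n, sAA + bg[["AA"]]),
    n_AD = stats::rpois(n, bg[["AD"]]))
  out$n_total <- out$n_DD + out$n_DA + out$n_AA + out$n_AD
  out
}

#' Simulate a single photon burst
#'
#' Draws the per-class photon counts of one burst from Poisson
#' distributions whose expectations invert the correction chain of
#' [correct_counts()] (see [burst_count_expectations()]), then places the
#' photons uniformly over the burst envelope with microtimes inside the
#' correct PIE window.
#'
#' @inheritParams burst_count_expectations
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return A [photon_stream()] fragment starting at time 0, without
#'   stream-level background (added by the stream assemblers).
#' @export
simulate_burst <- function(species, instrument, seed = NULL) {
  with_seed(seed, {
    cnt <- simulate_burst_counts(list(species), 1L, instrument,
                                 include_background = FALSE)
    burst_photon_fragment(cnt, instrument, start_s = 0)
  })
}

# Expand a counts table (signal only) into photon records.
burst_photon_fragment <- function(counts, instrument, start_s) {
  d <- instrument$mean_burst_duration
  split <- instrument$microtime_split
  period <- instrument$pie_period
  nDD <- counts$n_DD; nDA <- counts$n_DA; nAA <- counts$n_AA
  tot <- nDD + nDA + nAA
  t_s <- rep(start_s, times = tot) + stats::runif(sum(tot)) * d
  cls <- rep.int(rep.int(c("DD", "DA", "AA"), length(tot)),
                 as.vector(rbind(nDD, nDA, nAA)))
  channel <- ifelse(cls == "DD", "D", "A")
  micro <- numeric(sum(tot))
  dex <- cls != "AA"
  micro[dex] <- split + stats::runif(sum(dex)) * (period - split)
  micro[!dex] <- stats::runif(sum(!dex)) * split
  ticks <- round(t_s * instrument$clock_rate_hz)
  photon_stream(ticks, channel, micro,
                clock_rate_hz = instrument$clock_rate_hz, sort = TRUE)
}

# Stream-wide background photons over [0, duration_s], uniform microtimes.
background_photons <- function(instrument, duration_s) {
  rates <- instrument$background_rates
  n <- stats::rpois(2, rates * duration_s)
  ticks <- round(stats::runif(sum(n)) * duration_s * instrument$clock_rate_hz)
  photon_stream(ticks, rep(c("D", "A"), n),
                stats::runif(sum(n)) * instrument$pie_period,
                clock_rate_hz = instrument$clock_rate_hz, sort = TRUE)
}

# Merge photon fragments into one sorted stream.
combine_streams <- function(..., clock_rate_hz, metadata = list()) {
  parts <- list(...)
  ticks <- unlist(lapply(parts, `[[`, "ticks"), use.names = FALSE)
  channel <- unlist(lapply(parts, `[[`, "channel"), use.names = FALSE)
  micro <- unlist(lapply(parts, `[[`, "microtime_ns"), use.names = FALSE)
  photon_stream(ticks, channel, micro, clock_rate_hz = clock_rate_hz,
                metadata = metadata, sort = TRUE)
}

# Draw species indices for FRET-active + donor-only mixture at fraction fdec.
draw_species <- function(n, fdec, donor_only_fraction) {
  r <- stats::runif(n)
  id <- integer(n)
  don <- r < donor_only_fraction
  id[don] <- 3L
  dec <- !don & (stats::runif(n) < fdec)
  id[dec] <- 2L
  id[!don & !dec] <- 1L
  id
}

mixture_species_list <- function(course) {
  list(course$compact, course$decompacted,
       species_spec("donor-only", 0,
                    brightness_D_ex = course$compact$brightness_D_ex,
                    brightness_A_ex = course$compact$brightness_A_ex,
                    labeled_state = "donor-only"))
}

#' Simulate a droplet-mode kinetic series
#'
#' Generates, for each reaction time of a [mixture_time_course()], a burst
#' ensemble from the two-species mixture plus donor-only contaminants, with
#' the decompacted fraction evolving by the two-state law
#' ([two_state_fraction()]). Each burst's species is an independent draw
#' with `P(decompacted) = f_dec(t)` among FRET-active bursts. In
#' droplet-mixer experiments each time point corresponds to one position
#' along the observation channel and is recorded as its own photon stream.
#'
#' @param course A [mixture_time_course()].
#' @param instrument An [instrument_spec()].
#' @param bursts_per_timepoint Bursts per time point (experiments select at
#'   least 3000).
#' @param timestamps If `TRUE` return full timestamped [photon_stream()]s;
#'   if `FALSE` return per-burst count tables directly (fast path that
#'   bypasses photon placement and burst search).
#' @param burst_rate Mean burst arrival rate in the stream, bursts/s
#'   (photon-level path only).
#' @param seed Optional RNG seed; recorded in the ground-truth metadata.
#' @return A list of class `kinetic_series_sim` with elements `times`,
#'   `streams` (or `bursts` when `timestamps = FALSE`), `truth` (data frame
#'   of per-time true decompacted fraction and realised species counts),
#'   `course`, `instrument`, `seed`.
#' @export
#' @examples
#' sim <- simulate_kinetic_series(mixture_time_course(times = c(0.1, 1)),
#'                                instrument_spec(),
#'                                bursts_per_timepoint = 50, seed = 1)
#' sim$truth
simulate_kinetic_series <- function(course, instrument,
                                    bursts_per_timepoint = 3000,
                                    timestamps = TRUE, burst_rate = 100,
                                    seed = NULL) {
  stopifnot(inherits(course, "mixture_time_course"),
            inherits(instrument, "instrument_spec"))
  if (bursts_per_timepoint < 1) stop("bursts_per_timepoint must be >= 1")
  with_seed(seed, {
    species <- mixture_species_list(course)
    fdec <- two_state_fraction(course$times, course$k_obs, course$f0,
                               course$f_inf)
    out <- vector("list", length(course$times))
    truth_rows <- vector("list", length(course$times))
    for (i in seq_along(course$times)) {
      id <- draw_species(bursts_per_timepoint, fdec[i],
                         course$donor_only_fraction)
      counts <- simulate_burst_counts(species, id, instrument,
                                      include_background = !timestamps)
      truth_rows[[i]] <- data.frame(
        time = course$times[i], f_dec_true = fdec[i],
        n_bursts = bursts_per_timepoint,
        n_compact = sum(id == 1L), n_decompacted = sum(id == 2L),
        n_donor_only = sum(id == 3L))
      if (timestamps) {
        gap_floor <- 2 * 0.001 # keep neighbouring bursts in separate bins
        gaps <- gap_floor + stats::rexp(bursts_per_timepoint,
                                        rate = burst_rate)
        starts <- cumsum(gaps)
        total <- starts[bursts_per_timepoint] +
          instrument$mean_burst_duration + 0.005
        sig <- burst_photon_fragment(counts, instrument, start_s = starts)
        bg <- background_photons(instrument, total)
        out[[i]] <- combine_streams(
          sig, bg, clock_rate_hz = instrument$clock_rate_hz,
          metadata = list(truth = list(
            time = course$times[i], f_dec_true = fdec[i],
            species = counts$species, starts = starts, seed = seed)))
      } else {
        counts$start <- (seq_len(bursts_per_timepoint) - 1) * 0.01
        counts$stop <- counts$start + counts$duration
        out[[i]] <- counts
      }
    }
    res <- list(times = course$times, truth = do.call(rbind, truth_rows),
                course = course, instrument = instrument, seed = seed)
    if (timestamps) res$streams <- out else res$bursts <- out
    class(res) <- "kinetic_series_sim"
    res
  })
}

#' Simulate a slow manual-mixing trace
#'
#' Produces a single continuous photon stream in which burst arrivals are
#' Poisson with the given rate and each burst's species is drawn from the
#' mixture at its own reaction time, so the species fractions evolve
#' continuously along the trace. Reaction time is `t_start + arrival time`:
#' manual mixing takes a few seconds before recording starts.
#'
#' @inheritParams simulate_kinetic_series
#' @param duration Recorded duration, s (20 min = 1200 s typical).
#' @param burst_rate Mean burst rate, bursts/s (~16.7/s gives ~1000 bursts
#'   per one-minute window).
#' @param t_start Reaction time at the start of the recording, s.
#' @return A [photon_stream()] with ground truth in its metadata.
#' @export
simulate_slow_trace <- function(course, instrument, duration = 1200,
                                burst_rate = 1000 / 60, t_start = 5,
                                seed = NULL) {
  stopifnot(inherits(course, "mixture_time_course"),
            inherits(instrument, "instrument_spec"), duration > 0,
            burst_rate > 0, t_start >= 0)
  with_seed(seed, {
    n <- stats::rpois(1, burst_rate * duration)
    starts <- sort(stats::runif(n, 0, duration - 2 * instrument$mean_burst_duration))
    fdec <- two_state_fraction(t_start + starts, course$k_obs, course$f0,
                               course$f_inf)
    id <- integer(n)
    r <- stats::runif(n)
    don <- r < course$donor_only_fraction
    dec <- !don & (stats::runif(n) < fdec)
    id[don] <- 3L; id[dec] <- 2L; id[!don & !dec] <- 1L
    species <- mixture_species_list(course)
    counts <- simulate_burst_counts(species, id, instrument,
                                    include_background = FALSE)
    sig <- burst_photon_fragment(counts, instrument, start_s = starts)
    bg <- background_photons(instrument, duration)
    combine_streams(
      sig, bg, clock_rate_hz = instrument$clock_rate_hz,
      metadata = list(truth = list(
        course = course, t_start = t_start, duration = duration,
        starts = starts, species = counts$species, seed = seed)))
  })
}
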