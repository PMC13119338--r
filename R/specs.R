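#' Instrument description for PIE single-molecule detection
#'
#' Collects the timing and distortion parameters of a pulsed-interleaved-
#' excitation (PIE) confocal instrument. The default timing corresponds to a
#' 20 MHz pulse train (50 ns period) in which the acceptor-excitation pulse
#' arrives at microtime 0 and triggers the donor diode laser with a ~25 ns
#' delay, so photon microtimes below `microtime_split` belong to the
#' acceptor-excitation window and microtimes at or above it to the
#' donor-excitation window.
#'
#' @param pie_period Pulse period in ns (50 ns = 20 MHz repetition rate).
#' @param pulse_delay Delay of the donor pulse after the acceptor pulse, ns.
#' @param microtime_split Microtime boundary (ns) separating the
#'   acceptor-excitation window `[0, split)` from the donor-excitation
#'   window `[split, period)`. Defaults to `pulse_delay`.
#' @param background_rates Named numeric vector of dark/background count
#'   rates in photons/s for the two spectral detection channels `D` and `A`.
#'   Background photons are spread uniformly over the PIE period.
#' @param leakage_alpha Fraction of detected donor signal leaking into the
#'   acceptor channel (spectral crosstalk).
#' @param direct_excitation_delta Acceptor direct excitation by the donor
#'   laser, expressed as a fraction of the acceptor-excitation signal.
#' @param gamma Gamma factor (relative detection efficiency x quantum yield
#'   of acceptor vs donor).
#' @param mean_burst_duration Burst transit time through the confocal
#'   volume, in seconds.
#' @param clock_rate_hz Macrotime clock rate; timestamps are stored as
#'   integer ticks of this clock.
#'
#' @return An object of class `instrument_spec`.
#' @export
#' @examples
#' instr <- instrument_spec()
#' classify_pie(c(5, 30), instr)
instrument_spec <- function(pie_period = 50,
                            pulse_delay = 25,
                            microtime_split = pulse_delay,
                            background_rates = c(D = 1500, A = 1500),
                            leakage_alpha = 0.05,
                            direct_excitation_delta = 0.05,
                            gamma = 1.0,
                            mean_burst_duration = 1e-3,
                            clock_rate_hz = 1e7) {
  stopifnot(pie_period > 0, pulse_delay > 0, pie_period > pulse_delay,
            microtime_split > 0, microtime_split < pie_period,
            leakage_alpha >= 0, direct_excitation_delta >= 0, gamma > 0,
            mean_burst_duration > 0, clock_rate_hz > 0)
  if (is.null(names(background_rates)))
    names(background_rates) <- c("D", "A")
  stopifnot(all(c("D", "A") %in% names(background_rates)),
            all(background_rates >= 0))
  structure(list(
    pie_period = pie_period,
    pulse_delay = pulse_delay,
    microtime_split = microtime_split,
    background_rates = background_rates[c("D", "A")],
    leakage_alpha = leakage_alpha,
    direct_excitation_delta = direct_excitation_delta,
    gamma = gamma,
    mean_burst_duration = mean_burst_duration,
    clock_rate_hz = clock_rate_hz
  ), class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("PIE instrument: period", x$pie_period, "ns, donor pulse delayed",
      x$pulse_delay, "ns, split at", x$microtime_split, "ns\n")
  cat(sprintf("  background %.0f/%.0f Hz (D/A), alpha=%.3g, delta=%.3g, gamma=%.3g\n",
              x$background_rates[["D"]], x$background_rates[["A"]],
              x$leakage_alpha, x$direct_excitation_delta, x$gamma))
  invisible(x)
}

#' Fluorescent species for the synthetic photon generator
#'
#' Describes one molecular species by its corrected transfer efficiency and
#' mean burst brightness. `brightness_D_ex` is the mean *gamma-weighted*
#' detected signal per burst under donor excitation (the quantity conserved
#' across species of different E), `brightness_A_ex` the mean detected
#' acceptor signal per burst under acceptor excitation.
#'
#' @param name Species label.
#' @param true_E Ground-truth corrected transfer efficiency in \[0, 1\].
#' @param brightness_D_ex Mean detected photons per burst, donor excitation.
#' @param brightness_A_ex Mean detected photons per burst, acceptor
#'   excitation.
#' @param labeled_state `"double"`, `"donor-only"` or `"acceptor-only"`.
#' @return An object of class `species_spec`.
#' @export
#' @examples
#' species_spec("compact", true_E = 0.36)
species_spec <- function(name, true_E = 0.5,
                         brightness_D_ex = 80, brightness_A_ex = 80,
                         labeled_state = c("double", "donor-only",
                                           "acceptor-only")) {
  labeled_state <- match.arg(labeled_state)
  stopifnot(is.character(name), length(name) == 1,
            true_E >= 0, true_E <= 1,
            brightness_D_ex > 0, brightness_A_ex > 0)
  structure(list(name = name, true_E = true_E,
                 brightness_D_ex = brightness_D_ex,
                 brightness_A_ex = brightness_A_ex,
                 labeled_state = labeled_state),
            class = "species_spec")
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf("species '%s' (%s): E=%.3g, brightness D-ex %.3g / A-ex %.3g\n",
              x$name, x$labeled_state, x$true_E,
              x$brightness_D_ex, x$brightness_A_ex))
  invisible(x)
}

#' Two-state mixture evolving in reaction time
#'
#' A compact/decompacted two-species mixture whose decompacted fraction
#' follows the two-state pseudo-first-order law
#' `f_dec(t) = f_inf - (f_inf - f0) exp(-k_obs t)` (see
#' [two_state_fraction()]), plus a constant donor-only contaminant fraction.
#' Fractions apply to bursts: each burst is an independent draw with
#' `P(donor-only) = donor_only_fraction` and, among FRET-active bursts,
#' `P(decompacted) = f_dec(t)`.
#'
#' @param compact,decompacted [species_spec()] objects for the two
#'   FRET-active states. Defaults use the efficiencies of compact
#'   (E = 0.36) and decompacted (E = 0.053) nucleosomes.
#' @param f0 Decompacted fraction at t = 0.
#' @param f_inf Equilibrium decompacted fraction.
#' @param k_obs Observed pseudo-first-order rate, 1/s.
#' @param donor_only_fraction Constant donor-only contaminant fraction of
#'   all bursts (the S ~ 1 population removed by stoichiometry gating).
#' @param times Reaction times (s) at which droplet-mode histograms are
#'   acquired; must be non-negative and sorted.
#' @return An object of class `mixture_time_course`.
#' @export
#' @examples
#' mixture_time_course(k_obs = 0.42)
mixture_time_course <- function(compact = species_spec("compact", 0.36),
                                decompacted = species_spec("decompacted", 0.053),
                                f0 = 0.2, f_inf = 0.9, k_obs = 0.42,
                                donor_only_fraction = 0.15,
                                times = 10^seq(log10(0.01), log10(20),
                                               length.out = 8)) {
  stopifnot(inherits(compact, "species_spec"),
            inherits(decompacted, "species_spec"),
            f0 >= 0, f0 <= 1, f_inf >= 0, f_inf <= 1, k_obs >= 0,
            donor_only_fraction >= 0, donor_only_fraction < 1,
            all(times >= 0), !is.unsorted(times))
  structure(list(compact = compact, decompacted = decompacted,
                 f0 = f0, f_inf = f_inf, k_obs = k_obs,
                 donor_only_fraction = donor_only_fraction,
                 times = times),
            class = "mixture_time_course")
}

#' @export
print.mixture_time_course <- function(x, ...) {
  cat(sprintf("two-state mixture: f0=%.3g -> f_inf=%.3g at k_obs=%.3g /s; %d time points, %.0f%% donor-only\n",
              x$f0, x$f_inf, x$k_obs, length(x$times),
              100 * x$donor_only_fraction))
  invisible(x)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
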