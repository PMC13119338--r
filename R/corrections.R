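#' Correction factors for burst counts
#'
#' Defines the raw-to-corrected mapping of burst photon counts: background
#' rates per channel/excitation-window class, donor leakage into the
#' acceptor channel (`alpha`), acceptor direct excitation referenced to the
#' acceptor-excitation signal (`delta`, the natural PIE-based convention),
#' and the gamma factor correcting quantum-yield and detection-efficiency
#' imbalance.
#'
#' @param bg_rate_DD,bg_rate_DA,bg_rate_AA Background rates (photons/s) in
#'   the donor channel/donor-excitation, acceptor channel/donor-excitation
#'   and acceptor channel/acceptor-excitation classes.
#' @param alpha Leakage fraction (donor photons detected in the acceptor
#'   channel).
#' @param delta Direct-excitation fraction (proportional to the corrected
#'   acceptor-excitation signal `F_AA`).
#' @param gamma Gamma factor (> 0).
#' @return An object of class `correction_set`.
#' @seealso [correction_set_from_instrument()] derives the matching set for
#'   a synthetic [instrument_spec()].
#' @export
correction_set <- function(bg_rate_DD = 0, bg_rate_DA = 0, bg_rate_AA = 0,
                           alpha = 0, delta = 0, gamma = 1) {
  stopifnot(bg_rate_DD >= 0, bg_rate_DA >= 0, bg_rate_AA >= 0,
            alpha >= 0, delta >= 0, gamma > 0)
  structure(list(bg_rate_DD = bg_rate_DD, bg_rate_DA = bg_rate_DA,
                 bg_rate_AA = bg_rate_AA, alpha = alpha, delta = delta,
                 gamma = gamma),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat(sprintf(
    "corrections: bg %.3g/%.3g/%.3g Hz (DD/DA/AA), alpha=%.3g, delta=%.3g, gamma=%.3g\n",
    x$bg_rate_DD, x$bg_rate_DA, x$bg_rate_AA, x$alpha, x$delta, x$gamma))
  invisible(x)
}

#' Correction set matching a synthetic instrument
#'
#' Converts an [instrument_spec()] into the [correction_set()] that exactly
#' inverts the generator's distortion model, including the split of each
#' detection channel's background rate between the two PIE windows.
#'
#' @param instrument An [instrument_spec()].
#' @return A [correction_set()].
#' @export
correction_set_from_instrument <- function(instrument) {
  stopifnot(inherits(instrument, "instrument_spec"))
  bg <- background_window_rates(instrument)
  correction_set(bg_rate_DD = bg[["DD"]], bg_rate_DA = bg[["DA"]],
                 bg_rate_AA = bg[["AA"]], alpha = instrument$leakage_alpha,
                 delta = instrument$direct_excitation_delta,
                 gamma = instrument$gamma)
}

#' Correct burst counts for background, leakage and direct excitation
#'
#' Applies the standard PIE/ALEX correction chain to raw burst counts:
#' \deqn{F_{DD} = n_{DD} - b_{DD} d, \quad F_{AA} = n_{AA} - b_{AA} d,}
#' \deqn{F_{DA} = n_{DA} - b_{DA} d - \alpha F_{DD} - \delta F_{AA},}
#' with `d` the burst duration. With `clamp = TRUE` (the default contract),
#' negative corrected counts are clamped to zero and the burst flagged;
#' [fret_points()] uses the unclamped values for E (so shot noise can push
#' E slightly below zero) and the clamped values for S.
#'
#' @param bursts A `burst_table` from [find_bursts()] (columns `n_DD`,
#'   `n_DA`, `n_AA`, `duration`).
#' @param corr A [correction_set()].
#' @param clamp Clamp negative corrected counts to zero.
#' @return Data frame with `F_DD`, `F_DA`, `F_AA` and logical `clamped`.
#' @export
correct_counts <- function(bursts, corr, clamp = TRUE) {
  stopifnot(inherits(corr, "correction_set"),
            all(c("n_DD", "n_DA", "n_AA", "duration") %in% names(bursts)),
            all(bursts$duration > 0))
  d <- bursts$duration
  F_DD <- bursts$n_DD - corr$bg_rate_DD * d
  F_AA <- bursts$n_AA - corr$bg_rate_AA * d
  F_DA <- bursts$n_DA - corr$bg_rate_DA * d - corr$alpha * F_DD -
    corr$delta * F_AA
  clamped <- (F_DD < 0) | (F_AA < 0) | (F_DA < 0)
  out <- data.frame(F_DD = F_DD, F_DA = F_DA, F_AA = F_AA,
                    clamped = clamped)
  if (clamp) {
    out$F_DD <- pmax(out$F_DD, 0)
    out$F_DA <- pmax(out$F_DA, 0)
    out$F_AA <- pmax(out$F_AA, 0)
  }
  out
}

#' Transfer efficiency from corrected counts
#'
#' `E = F_DA / (gamma * F_DD + F_DA)`, which reduces to the uncorrected
#' estimator `n_A / (n_A + n_D)` when all correction factors vanish and
#' gamma = 1.
#'
#' @param F_DD,F_DA Corrected donor- and acceptor-channel counts under
#'   donor excitation.
#' @param gamma Gamma factor.
#' @return Transfer efficiencies; `NA` where the denominator is <= 0
#'   (undefined point, to be excluded).
#' @export
#' @examples
#' transfer_efficiency(100, 25, gamma = 1.2) # 25/145
transfer_efficiency <- function(F_DD, F_DA, gamma = 1) {
  stopifnot(gamma > 0)
  den <- gamma * F_DD + F_DA
  ifelse(den > 0, F_DA / den, NA_real_)
}

#' Stoichiometry ratio from corrected counts
#'
#' `S = (gamma * F_DD + F_DA) / (gamma * F_DD + F_DA + F_AA)`: the fraction
#' of donor-excitation signal relative to the total including
#' acceptor-excitation photons. Donor-only molecules give S ~ 1,
#' acceptor-only S ~ 0, doubly labeled molecules S ~ 0.5 under balanced
#' excitation.
#'
#' @inheritParams transfer_efficiency
#' @param F_AA Corrected acceptor-channel counts under acceptor excitation.
#' @return Stoichiometry ratios; `NA` where the denominator is <= 0.
#' @export
stoichiometry <- function(F_DD, F_DA, F_AA, gamma = 1) {
  stopifnot(gamma > 0)
  dex <- gamma * F_DD + F_DA
  den <- dex + F_AA
  ifelse(den > 0, dex / den, NA_real_)
}

#' Per-burst corrected FRET coordinates
#'
#' Combines [correct_counts()], [transfer_efficiency()] and
#' [stoichiometry()] into the per-burst (E, S) table used by histogram
#' fitting and gating. E is computed from unclamped corrected counts (so a
#' zero-transfer population is centred on its true efficiency rather than
#' piled up at zero); S from counts clamped at zero, so S lies in \[0, 1\].
#'
#' @param bursts A `burst_table`.
#' @param corr A [correction_set()].
#' @return Data frame of class `fret_points`: `E`, `S`, `n_total`
#'   (corrected donor-excitation photons, `F_DD + F_DA`), `clamped`, plus
#'   the source burst index `burst`. Bursts with undefined E are dropped.
#' @export
fret_points <- function(bursts, corr) {
  raw <- correct_counts(bursts, corr, clamp = FALSE)
  cl <- data.frame(F_DD = pmax(raw$F_DD, 0), F_DA = pmax(raw$F_DA, 0),
                   F_AA = pmax(raw$F_AA, 0))
  E <- transfer_efficiency(raw$F_DD, raw$F_DA, corr$gamma)
  S <- stoichiometry(cl$F_DD, cl$F_DA, cl$F_AA, corr$gamma)
  out <- data.frame(E = E, S = S, n_total = raw$F_DD + raw$F_DA,
                    F_AA = cl$F_AA, duration = bursts$duration,
                    clamped = raw$clamped, burst = seq_len(nrow(bursts)))
  keep <- !is.na(out$E)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fret_points", "data.frame")
  out
}

#' Gate FRET points by stoichiometry
#'
#' Keeps bursts with `s_low < S < s_high` (strictly inside, open interval),
#' removing donor-only (S ~ 1) and acceptor-only (S ~ 0) molecules.
#' Standard gates: 0.2 < S < 0.8 for the labeled-nucleosome experiments,
#' 0.25 < S < 0.75 for the intermolecular-FRET experiment.
#'
#' @param points A `fret_points` data frame (or any data frame with an `S`
#'   column).
#' @param s_low,s_high Gate bounds, `0 <= s_low < s_high <= 1`.
#' @return The gated subset.
#' @export
gate_stoichiometry <- function(points, s_low = 0.2, s_high = 0.8) {
  stopifnot(s_low >= 0, s_high <= 1, s_low < s_high, "S" %in% names(points))
  keep <- !is.na(points$S) & points$S > s_low & points$S < s_high
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
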