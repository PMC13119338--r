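#' Förster efficiency from an inter-dye distance
#'
#' The Förster relation `E(r) = 1 / (1 + (r / R0)^6)`, with R0 the
#' Förster radius of the dye pair (5.4 nm for the Alexa 488/594 pair used
#' for nucleosome labelling).
#'
#' @param r Inter-dye distances, nm (> 0).
#' @param R0 Förster radius, nm.
#' @return Transfer efficiencies.
#' @export
#' @examples
#' forster_efficiency(5.4)        # 0.5 at r = R0
#' forster_efficiency(10.8)       # 1/65
forster_efficiency <- function(r, R0 = 5.4) {
  stopifnot(R0 > 0)
  if (any(r <= 0)) stop("distances must be positive")
  1 / (1 + (r / R0)^6)
}

#' Ensemble-mean Förster efficiency of a distance series
#'
#' Arithmetic mean of the per-frame efficiencies (the ensemble average of
#' E, not E of the mean distance), as used to compare simulated dye-dye
#' distance trajectories with experimental transfer efficiencies.
#'
#' @param r Per-frame inter-dye distances, nm.
#' @param R0 Förster radius, nm.
#' @return Mean transfer efficiency.
#' @export
mean_efficiency <- function(r, R0 = 5.4) {
  if (!length(r)) stop("empty distance series")
  mean(forster_efficiency(r, R0))
}

#' Count intermolecular contacts between two bead groups
#'
#' Number of pairs (a in A, b in B) closer than the cutoff (1.2 nm by
#' convention for coarse-grained nucleosome/PAR models). The comparison is
#' a strict inequality at the cutoff.
#'
#' @param coords_A,coords_B Numeric matrices (n x d) of bead coordinates
#'   for the two groups, in nm.
#' @param cutoff Contact distance cutoff, nm.
#' @return Integer contact count (0 if either group is empty).
#' @export
count_contacts <- function(coords_A, coords_B, cutoff = 1.2) {
  stopifnot(cutoff > 0)
  coords_A <- as.matrix(coords_A); coords_B <- as.matrix(coords_B)
  if (!nrow(coords_A) || !nrow(coords_B)) return(0L)
  stopifnot(ncol(coords_A) == ncol(coords_B),
            all(is.finite(coords_A)), all(is.finite(coords_B)))
  d2 <- outer(rowSums(coords_A^2), rowSums(coords_B^2), `+`) -
    2 * tcrossprod(coords_A, coords_B)
  sum(d2 < cutoff^2 - .Machine$double.eps^0.5)
}

#' Mean lifetime of a contact time series
#'
#' Mean duration of maximal runs of `TRUE` in a per-frame contact
#' indicator, in time units of `frame_dt`. Runs touching the series
#' boundaries are included.
#'
#' @param contact Logical vector, contact present per frame.
#' @param frame_dt Frame spacing, in time units.
#' @return Mean continuous-contact duration; 0 (with attribute
#'   `no_contacts = TRUE`) if no contact ever forms.
#' @export
#' @examples
#' contact_lifetime(c(TRUE, TRUE, FALSE, TRUE), frame_dt = 1) # 1.5
contact_lifetime <- function(contact, frame_dt = 1) {
  stopifnot(length(contact) >= 1, is.logical(contact), frame_dt > 0)
  r <- rle(contact)
  runs <- r$lengths[r$values]
  if (!length(runs)) {
    out <- 0
    attr(out, "no_contacts") <- TRUE
    return(out)
  }
  mean(runs) * frame_dt
}

#' Umbrella-sampling window
#'
#' One biased replica of an umbrella-sampling run: samples of the reaction
#' coordinate under a harmonic bias `U(x) = k/2 (x - center)^2`. The
#' reference layout uses 16 equally spaced windows with a force constant
#' of 10 kJ/mol/nm^2 over 0-16 nm.
#'
#' @param center Bias centre, nm.
#' @param samples Reaction-coordinate samples, nm (>= 1).
#' @param force_constant Bias force constant, kJ/mol/nm^2.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, samples, force_constant = 10) {
  stopifnot(force_constant > 0, length(samples) >= 1,
            all(is.finite(samples)))
  structure(list(center = center, force_constant = force_constant,
                 samples = as.numeric(samples)),
            class = "umbrella_window")
}

#' Potential of mean force by the weighted histogram analysis method
#'
#' Combines harmonic umbrella windows into an unbiased potential of mean
#' force by self-consistent WHAM iteration over the per-window free-energy
#' offsets, stopping when the largest offset change falls below
#' `tolerance` (kJ/mol). The PMF is reported with its minimum set to zero.
#'
#' @param windows List of [umbrella_window()] objects (>= 2, overlapping).
#' @param n_bins Number of histogram bins over the sampled range.
#' @param temperature Temperature, K.
#' @param tolerance Convergence tolerance on the offsets, kJ/mol.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Data frame with bin centres `x` (nm), `pmf` (kJ/mol), total
#'   bin counts `n`, plus attributes `offsets` (kJ/mol per window) and
#'   `iterations`.
#' @export
wham_pmf <- function(windows, n_bins = 200, temperature = 300,
                     tolerance = 1e-7, max_iter = 100000) {
  stopifnot(length(windows) >= 2,
            all(vapply(windows, inherits, logical(1), "umbrella_window")),
            n_bins >= 2, temperature > 0, tolerance > 0)
  kT <- 0.008314462618 * temperature # kJ/mol
  all_x <- unlist(lapply(windows, `[[`, "samples"), use.names = FALSE)
  rng <- range(all_x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  edges[n_bins + 1] <- edges[n_bins + 1] + 1e-9
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  W <- length(windows)
  counts <- vapply(windows, function(w)
    tabulate(findInterval(w$samples, edges), nbins = n_bins),
    numeric(n_bins)) # n_bins x W
  # overlap diagnostic: sorted-by-centre neighbours must share occupied bins
  occ <- counts > 0
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  for (i in seq_len(W - 1)) {
    if (!any(occ[, ord[i]] & occ[, ord[i + 1]]))
      stop(sprintf("umbrella windows %d and %d (by centre) do not overlap",
                   i, i + 1))
  }
  N <- colSums(counts)
  bias <- vapply(windows, function(w)
    0.5 * w$force_constant * (mids - w$center)^2, numeric(n_bins))
  cmat <- exp(-bias / kT) # n_bins x W
  M <- rowSums(counts)
  f <- numeric(W) # free-energy offsets, kJ/mol
  for (it in seq_len(max_iter)) {
    denom <- as.vector(cmat %*% (N * exp(f / kT)))
    p <- ifelse(denom > 0, M / denom, 0)
    z <- as.vector(crossprod(cmat, p))
    f_new <- -kT * log(z)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance) break
  }
  if (delta >= tolerance)
    stop("WHAM did not converge within the iteration cap")
  denom <- as.vector(cmat %*% (N * exp(f / kT)))
  p <- ifelse(denom > 0 & M > 0, M / denom, NA_real_)
  pmf <- -kT * log(p)
  pmf <- pmf - min(pmf, na.rm = TRUE)
  out <- data.frame(x = mids, pmf = pmf, n = M)
  attr(out, "offsets") <- f
  attr(out, "iterations") <- it
  out
}
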