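#' Transfer-efficiency histogram
#'
#' Bins per-burst transfer efficiencies on a fixed E axis. The default
#' axis extends beyond \[0, 1\] because corrected efficiencies can fall
#' slightly outside it through shot noise; the default 0.025 bin width
#' resolves peak pairs such as 0.05/0.36 with a few thousand bursts.
#'
#' @param E Per-burst transfer efficiencies (e.g. `fret_points$E`).
#' @param bin_width Bin width on the E axis.
#' @param range E-axis range (values outside are dropped).
#' @param timepoint Reaction time (s) or label attached to the histogram.
#' @return Object of class `efficiency_histogram`: list with `edges`,
#'   `mids`, `counts`, `n_bursts`, `timepoint`.
#' @export
efficiency_histogram <- function(E, bin_width = 0.025,
                                 range = c(-0.1, 1.1), timepoint = NA) {
  stopifnot(bin_width > 0, length(range) == 2, range[1] < range[2])
  edges <- seq(range[1], range[2] + bin_width / 2, by = bin_width)
  E <- E[!is.na(E) & E >= edges[1] & E < edges[length(edges)]]
  idx <- findInterval(E, edges)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  structure(list(edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_bursts = sum(counts),
                 timepoint = timepoint),
            class = "efficiency_histogram")
}

#' @export
print.efficiency_histogram <- function(x, ...) {
  cat(sprintf("efficiency histogram: %d bursts in %d bins [%.3g, %.3g]",
              x$n_bursts, length(x$counts), x$edges[1],
              x$edges[length(x$edges)]))
  if (!is.na(x$timepoint)) cat(sprintf(", t = %.4g s", as.numeric(x$timepoint)))
  cat("\n")
  invisible(x)
}

#' Shot-noise width of a FRET-efficiency peak
#'
#' The minimum width of a transfer-efficiency peak arising from binomial
#' photon-counting statistics: `sigma = sqrt(E (1 - E) / N)` for mean
#' efficiency E and N photons per burst.
#'
#' @param E Mean transfer efficiency in \[0, 1\].
#' @param N Photons per burst (>= 1); typically the median corrected
#'   donor-excitation photon count of the dataset.
#' @return Peak standard deviation in E units.
#' @export
#' @examples
#' shot_noise_sigma(0.5, 100) # 0.05
shot_noise_sigma <- function(E, N) {
  stopifnot(all(E >= 0), all(E <= 1))
  if (any(N < 1)) stop("N must be >= 1")
  sqrt(E * (1 - E) / N)
}

#' Reference photon count for shot-noise widths
#'
#' Since peak variance scales as 1/N, the width of a peak built from
#' bursts of varying size equals the width evaluated at the *harmonic*
#' mean photon count (the mixture variance is the mean of the per-N
#' variances). The harmonic mean is therefore the default statistic;
#' median and mean are available for comparison.
#'
#' @param points A `fret_points` data frame.
#' @param statistic `"harmonic"` (default), `"median"` or `"mean"` of the
#'   corrected donor-excitation photon counts.
#' @return Scalar N entering [shot_noise_sigma()].
#' @export
n_ref_photons <- function(points,
                          statistic = c("harmonic", "median", "mean")) {
  statistic <- match.arg(statistic)
  n <- points$n_total[points$n_total >= 1]
  if (!length(n)) stop("no bursts with positive corrected counts")
  switch(statistic,
         harmonic = 1 / mean(1 / n),
         median = stats::median(n),
         mean = mean(n))
}

#' Shot-noise peak width propagated through the correction chain
#'
#' Expected standard deviation of a corrected-efficiency peak from photon
#' counting statistics alone. Beyond the binomial partition noise of
#' [shot_noise_sigma()], the raw acceptor count also contains leakage,
#' direct-excitation and background photons that are subtracted only in
#' expectation; their Poisson noise (and its covariance with the donor
#' count through the leakage term) broadens the corrected histogram, and
#' dominates it for low-E populations when the correction terms rival the
#' FRET signal. First-order propagation through
#' `E = F_DA / (gamma F_DD + F_DA)` gives the width used to constrain the
#' global fit; it reduces exactly to `sqrt(E (1 - E) / N)` when all
#' corrections vanish.
#'
#' @param E Mean transfer efficiency in \[0, 1\].
#' @param N Corrected donor-excitation photons per burst (see
#'   [n_ref_photons()]).
#' @param corr A [correction_set()].
#' @param A_ref Typical corrected acceptor-excitation count per burst
#'   (median `F_AA`); sets the direct-excitation noise term.
#' @param d_ref Typical burst duration, s; sets the background terms.
#' @return Peak standard deviation in E units.
#' @export
shot_noise_sigma_corrected <- function(E, N, corr, A_ref = 0,
                                       d_ref = 0) {
  stopifnot(inherits(corr, "correction_set"), all(E >= 0), all(E <= 1),
            A_ref >= 0, d_ref >= 0)
  if (any(N < 1)) stop("N must be >= 1")
  g <- corr$gamma; a <- corr$alpha; dl <- corr$delta
  lamDD <- (1 - E) * N / g + corr$bg_rate_DD * d_ref
  lamAA <- A_ref + corr$bg_rate_AA * d_ref
  lamDA <- E * N + a * (1 - E) * N / g + dl * A_ref +
    corr$bg_rate_DA * d_ref
  varU <- lamDA + a^2 * lamDD + dl^2 * lamAA # var of F_DA
  varV <- g^2 * lamDD                        # var of gamma F_DD
  covUV <- -a * g * lamDD
  u <- E * N; v <- (1 - E) * N
  sqrt(pmax(v^2 * varU + u^2 * varV - 2 * u * v * covUV, 0)) / N^2
}

# Deterministic initial peak positions: local maxima of the pooled,
# lightly smoothed histogram, tallest first, reordered ascending.
init_peak_positions <- function(hists, peaks) {
  counts <- Reduce(`+`, lapply(hists, `[[`, "counts"))
  mids <- hists[[1]]$mids
  k <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  k[is.na(k)] <- counts[is.na(k)]
  n <- length(k)
  is_max <- k >= c(-Inf, k[-n]) & k >= c(k[-1], -Inf) & counts > 0
  cand <- mids[is_max][order(k[is_max], decreasing = TRUE)]
  # enforce separation so one broad peak is not picked twice
  sep <- 4 * (mids[2] - mids[1])
  mu <- numeric(0)
  for (m in cand) {
    if (all(abs(m - mu) > sep)) mu <- c(mu, m)
    if (length(mu) == peaks) break
  }
  while (length(mu) < peaks) # degenerate data: spread remaining guesses
    mu <- c(mu, mids[which.max(counts)] + 0.3 * length(mu))
  sort(pmin(pmax(mu, mids[1]), mids[length(mids)]))
}

#' Global shot-noise-constrained Gaussian fit of efficiency histograms
#'
#' Fits all histograms of a kinetic series simultaneously with `peaks`
#' Gaussian peak functions. Peak positions are shared across histograms;
#' peak widths are constrained to the shot-noise values
#' `shot_noise_sigma(mu, n_ref)` (recomputed from the current positions at
#' every iteration); per-histogram amplitudes are free and non-negative.
#' The objective is least squares on bin counts with Poisson-approximate
#' weights `1/sqrt(max(count, 1))`, minimised with the Levenberg-Marquardt
#' algorithm ([minpack.lm::nls.lm]).
#'
#' @param hists An `efficiency_histogram` or list of them (shared edges).
#' @param n_ref Reference photon count for the shot-noise widths (see
#'   [n_ref_photons()]).
#' @param peaks Number of Gaussian peaks (2 for a compact/decompacted
#'   mixture; 1 for single-population samples).
#' @param init_mu Optional initial peak positions; defaults to modes of
#'   the pooled histogram (ordered ascending).
#' @param sigma_fun Width constraint: a function mapping peak positions
#'   to peak standard deviations. Defaults to the binomial width
#'   `shot_noise_sigma(mu, n_ref)`; pipelines pass the
#'   correction-propagated width ([shot_noise_sigma_corrected()]).
#' @return Object of class `fret_hist_fit`: shared positions `mu` (sorted
#'   ascending; for two peaks the high-E peak is the compact population),
#'   `sigma`, amplitude matrix, per-histogram `fractions` data frame
#'   (`timepoint`, `fraction_compact`, `se`), parameter covariance, and
#'   convergence diagnostics.
#' @export
fit_efficiency_histograms <- function(hists, n_ref, peaks = 2,
                                      init_mu = NULL, sigma_fun = NULL) {
  if (inherits(hists, "efficiency_histogram")) hists <- list(hists)
  stopifnot(length(hists) >= 1, peaks >= 1, n_ref >= 1,
            all(vapply(hists, inherits, logical(1), "efficiency_histogram")))
  edges1 <- hists[[1]]$edges
  for (h in hists) stopifnot(isTRUE(all.equal(h$edges, edges1)))
  H <- length(hists)
  mids <- hists[[1]]$mids
  counts <- lapply(hists, `[[`, "counts")
  w <- lapply(counts, function(cc) 1 / sqrt(pmax(cc, 1)))
  if (is.null(init_mu)) init_mu <- init_peak_positions(hists, peaks)
  stopifnot(length(init_mu) == peaks, !is.unsorted(init_mu),
            !anyDuplicated(init_mu))
  # initial amplitudes: pooled counts at the bins nearest each position
  amp0 <- vapply(seq_len(peaks), function(j) {
    i <- which.min(abs(mids - init_mu[j]))
    vapply(counts, function(cc) max(cc[i], 1), numeric(1))
  }, numeric(H))
  amp0 <- matrix(amp0, nrow = H)
  par0 <- c(pmin(pmax(init_mu, 0), 1), as.vector(t(amp0)))
  if (is.null(sigma_fun))
    sigma_fun <- function(mu) shot_noise_sigma(mu, n_ref)
  model_counts <- function(par) {
    mu <- par[seq_len(peaks)]
    sig <- sigma_fun(pmin(pmax(mu, 0), 1))
    sig <- pmax(sig, 1e-4) # keep peaks at E = 0 or 1 finite-width
    amps <- matrix(par[-seq_len(peaks)], nrow = H, byrow = TRUE)
    lapply(seq_len(H), function(i) {
      y <- 0
      for (j in seq_len(peaks))
        y <- y + amps[i, j] * exp(-(mids - mu[j])^2 / (2 * sig[j]^2))
      y
    })
  }
  resid_fun <- function(par) {
    m <- model_counts(par)
    unlist(lapply(seq_len(H), function(i) (m[[i]] - counts[[i]]) * w[[i]]),
           use.names = FALSE)
  }
  lower <- c(rep(0, peaks), rep(0, H * peaks))
  upper <- c(rep(1, peaks), rep(Inf, H * peaks))
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, maxfev = 20000,
                              ftol = 1e-12, ptol = 1e-12))
  if (!fit$info %in% 1:4)
    stop("global histogram fit did not converge: ", fit$message)
  par <- fit$par
  o <- order(par[seq_len(peaks)])
  mu <- par[seq_len(peaks)][o]
  sig <- pmax(sigma_fun(pmin(pmax(mu, 0), 1)), 1e-4)
  amps <- matrix(par[-seq_len(peaks)], nrow = H, byrow = TRUE)[, o,
                                                              drop = FALSE]
  # covariance from the weighted-residual jacobian at the optimum
  vc <- fit_covariance(resid_fun, par, length(unlist(counts)))
  # reorder covariance to match sorted peaks
  perm <- c(o, peaks + as.vector(vapply(seq_len(H), function(i)
    (i - 1) * peaks + o, numeric(peaks))))
  vc <- vc[perm, perm, drop = FALSE]
  fractions <- data.frame(
    timepoint = vapply(hists, function(h) as.numeric(h$timepoint[1]),
                       numeric(1)),
    fraction_compact = NA_real_, se = NA_real_)
  if (peaks == 2) {
    for (i in seq_len(H)) {
      u <- amps[i, 2] * sig[2] # high-E (compact) area, up to sqrt(2*pi)
      v <- amps[i, 1] * sig[1]
      f <- if (u + v > 0) u / (u + v) else NA_real_
      # delta method over the two amplitudes
      ii <- peaks + (i - 1) * peaks + c(1, 2) # (low, high) amp indices
      gr <- c(-sig[1] * u, sig[2] * v) / (u + v)^2
      se <- sqrt(max(0, drop(t(gr) %*% vc[ii, ii] %*% gr)))
      fractions$fraction_compact[i] <- f
      fractions$se[i] <- se
    }
  }
  structure(list(mu = mu, sigma = sig, amplitudes = amps,
                 fractions = fractions, n_ref = n_ref, peaks = peaks,
                 cov = vc, info = fit$info, message = fit$message,
                 deviance = fit$deviance, niter = fit$niter),
            class = "fret_hist_fit")
}

# Finite-difference jacobian -> covariance of the weighted LS estimate.
fit_covariance <- function(resid_fun, par, n_obs) {
  p <- length(par)
  r0 <- resid_fun(par)
  J <- matrix(0, length(r0), p)
  h <- pmax(abs(par), 1e-3) * 1e-6
  for (k in seq_len(p)) {
    pp <- par; pp[k] <- pp[k] + h[k]
    J[, k] <- (resid_fun(pp) - r0) / h[k]
  }
  s2 <- sum(r0^2) / max(1, n_obs - p)
  jtj <- crossprod(J)
  inv <- tryCatch(solve(jtj), error = function(e)
    solve(jtj + diag(1e-10 * max(diag(jtj)), p)))
  s2 * inv
}

#' @export
print.fret_hist_fit <- function(x, ...) {
  cat(sprintf("global histogram fit: %d peak(s) over %d histogram(s)\n",
              x$peaks, nrow(x$amplitudes)))
  cat("  positions:", sprintf("%.4f", x$mu),
      " shot-noise widths:", sprintf("%.4f", x$sigma),
      sprintf(" (N_ref = %.3g)\n", x$n_ref))
  if (x$peaks == 2 && nrow(x$fractions)) {
    cat("  fraction compact (high-E peak area):\n")
    print(format(x$fractions, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Compact fraction from a histogram fit
#'
#' The fraction of the compact (high-efficiency) population, determined
#' from the fractional area of the high-E Gaussian peak:
#' `A_high sigma_high / (A_high sigma_high + A_low sigma_low)`.
#'
#' @param fit A `fret_hist_fit` with two peaks.
#' @param timepoint Timepoint label of the histogram (must match one used
#'   in the fit); if `NULL` and the fit has a single histogram, that one.
#' @return Named numeric: `fraction_compact` and `se`.
#' @export
fraction_compact <- function(fit, timepoint = NULL) {
  stopifnot(inherits(fit, "fret_hist_fit"))
  if (fit$peaks != 2)
    stop("fraction_compact requires a two-peak fit")
  fr <- fit$fractions
  if (is.null(timepoint)) {
    if (nrow(fr) != 1) stop("specify the timepoint")
    i <- 1L
  } else {
    i <- match(as.numeric(timepoint), fr$timepoint)
    if (is.na(i)) stop("timepoint not present in the fit")
  }
  c(fraction_compact = fr$fraction_compact[i], se = fr$se[i])
}
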