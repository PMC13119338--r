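test_that("shot-noise width is the binomial counting width", {
  expect_equal(shot_noise_sigma(0.5, 100), 0.05)
  expect_equal(shot_noise_sigma(0, 50), 0)
  expect_equal(shot_noise_sigma(1, 50), 0)
  expect_equal(shot_noise_sigma(0.36, 80), sqrt(0.36 * 0.64 / 80))
  expect_error(shot_noise_sigma(0.5, 0.5), "N")
  # the correction-propagated width reduces to it without corrections
  expect_equal(shot_noise_sigma_corrected(c(0.2, 0.7), 90,
                                          correction_set()),
               shot_noise_sigma(c(0.2, 0.7), 90))
  # and is wider once correction noise is present
  co <- correction_set(alpha = 0.05, delta = 0.05, bg_rate_DA = 750)
  expect_true(all(shot_noise_sigma_corrected(c(0.05, 0.36), 80, co,
                                             A_ref = 80, d_ref = 1e-3) >
                    shot_noise_sigma(c(0.05, 0.36), 80)))
})

test_that("efficiency histograms conserve bursts on a fixed axis", {
  E <- c(-0.05, 0, 0.3, 0.3, 0.99, 1.05, 2) # last value out of range
  h <- efficiency_histogram(E, bin_width = 0.025)
  expect_equal(h$n_bursts, 6)
  expect_equal(sum(h$counts), h$n_bursts)
  expect_true(all(diff(h$edges) > 0))
})

test_that("noiseless two-Gaussian histograms are fitted exactly", {
  # counts generated from the model itself: amplitudes (1, 3) with
  # sigmas (0.04, 0.05); fractional area of the high peak is
  # 3*0.05 / (3*0.05 + 1*0.04) = 0.7894737
  mids <- efficiency_histogram(numeric(0))$mids
  sig <- c(0.04, 0.05)
  sigma_fun <- function(mu) sig
  y <- 1 * exp(-(mids - 0.06)^2 / (2 * sig[1]^2)) +
    3 * exp(-(mids - 0.36)^2 / (2 * sig[2]^2))
  h <- efficiency_histogram(numeric(0))
  h$counts <- round(y * 400)
  h$n_bursts <- sum(h$counts)
  fit <- fit_efficiency_histograms(h, n_ref = 80, peaks = 2,
                                   init_mu = c(0.1, 0.3),
                                   sigma_fun = sigma_fun)
  expect_equal(unname(fit$mu), c(0.06, 0.36), tolerance = 1e-3)
  f <- fraction_compact(fit)
  expect_equal(unname(f["fraction_compact"]), 0.15 / 0.19,
               tolerance = 5e-3)
})

test_that("single-species data drive one amplitude to zero", {
  instr <- default_instr
  corr <- correction_set_from_instrument(instr)
  pts <- sim_species_points(0.36, n = 6000, seed = 31)
  fit <- fit_population_histograms(pts, corr = corr, peaks = 2)
  # the vestigial peak carries ~no area; the dominant one sits at truth
  area <- colSums(fit$amplitudes) * fit$sigma
  dom <- which.max(area)
  expect_gt(area[dom] / sum(area), 0.97)
  expect_lt(abs(fit$mu[dom] - 0.36), 0.01)
})

test_that("a 50/50 mixture yields fraction 0.5 within binomial error", {
  instr <- default_instr
  corr <- correction_set_from_instrument(instr)
  sp <- list(species_spec("compact", 0.36),
             species_spec("decompacted", 0.053))
  cnt <- withr::with_seed(12,
    fretburst:::simulate_burst_counts(sp, rep(1:2, each = 3000), instr))
  pts <- fret_points(cnt, corr)
  fit <- fit_population_histograms(pts, corr = corr)
  f <- fraction_compact(fit)[["fraction_compact"]]
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 6000) + 0.02)
  # and fitted fractions are stable under bin-width changes (0.01-0.03)
  fr <- vapply(c(0.01, 0.02, 0.03), function(w) {
    fraction_compact(
      fit_population_histograms(pts, corr = corr,
                                bin_width = w))[["fraction_compact"]]
  }, numeric(1))
  expect_lt(max(fr) - min(fr), 0.04)
})

test_that("peak positions and fractions are recovered over replicates", {
  instr <- default_instr
  corr <- correction_set_from_instrument(instr)
  sp <- list(species_spec("compact", 0.36),
             species_spec("decompacted", 0.053))
  for (frac in c(0.5, 0.3)) {
    rec <- withr::with_seed(round(100 * frac), {
      vapply(1:50, function(r) {
        n_hi <- rbinom(1, 3000, frac)
        id <- c(rep(1L, n_hi), rep(2L, 3000 - n_hi))
        cnt <- fretburst:::simulate_burst_counts(sp, id, instr)
        fit <- fit_population_histograms(fret_points(cnt, corr),
                                         corr = corr)
        c(fit$mu, fraction_compact(fit)[["fraction_compact"]])
      }, numeric(3))
    })
    expect_lt(abs(mean(rec[1, ]) - 0.053), 0.01)
    expect_lt(abs(mean(rec[2, ]) - 0.36), 0.01)
    expect_lt(abs(mean(rec[3, ]) - frac), 0.03)
  }
})

test_that("fits are reproducible and degenerate inputs are handled", {
  pts <- sim_species_points(0.36, n = 2000, seed = 77)
  corr <- correction_set_from_instrument(default_instr)
  f1 <- fit_population_histograms(pts, corr = corr)
  f2 <- fit_population_histograms(pts, corr = corr)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$amplitudes, f2$amplitudes)
  expect_error(fraction_compact(f1, timepoint = 99), "timepoint")
  f3 <- fit_population_histograms(pts, corr = corr, peaks = 1)
  expect_error(fraction_compact(f3), "two-peak")
})
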