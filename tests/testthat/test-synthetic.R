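test_that("expected burst counts invert the correction chain", {
  instr0 <- instrument_spec(background_rates = c(D = 0, A = 0),
                            leakage_alpha = 0, direct_excitation_delta = 0,
                            gamma = 1)
  # zero transfer: no acceptor photons under donor excitation
  e0 <- burst_count_expectations(species_spec("dna", 0), instr0)
  expect_equal(e0$raw[["DA"]], 0)
  # complete transfer: no donor photons
  e1 <- burst_count_expectations(species_spec("x", 1), instr0)
  expect_equal(e1$raw[["DD"]], 0)

  # hand arithmetic at E = 0.36, B_D = 100, alpha = delta = 0.05,
  # gamma = 1.2 (signal part only): sig_DD = 0.64*100/1.2, sig_DA = 36,
  # raw_DA = 36 + 0.05*53.333 + 0.05*B_A
  instr <- instrument_spec(background_rates = c(D = 0, A = 0),
                           gamma = 1.2)
  sp <- species_spec("compact", 0.36, brightness_D_ex = 100,
                     brightness_A_ex = 100)
  e <- burst_count_expectations(sp, instr)
  expect_equal(e$signal[["DD"]], 64 / 1.2)
  expect_equal(e$raw[["DA"]], 36 + 0.05 * 64 / 1.2 + 0.05 * 100)
  # round trip: correcting the expectations recovers E exactly
  corr <- correction_set_from_instrument(instr)
  E_back <- transfer_efficiency(
    e$raw[["DD"]],
    e$raw[["DA"]] - corr$alpha * e$raw[["DD"]] - corr$delta * e$raw[["AA"]],
    gamma = 1.2)
  expect_equal(E_back, 0.36, tolerance = 1e-12)
})

test_that("donor-only and acceptor-only species have silent channels", {
  instr0 <- instrument_spec(background_rates = c(D = 0, A = 0))
  d <- burst_count_expectations(
    species_spec("d", 0, labeled_state = "donor-only"), instr0)
  expect_equal(unname(d$raw[c("DA", "AA")] -
                        c(instr0$leakage_alpha * d$signal[["DD"]], 0)),
               c(0, 0))
  a <- burst_count_expectations(
    species_spec("a", 0, labeled_state = "acceptor-only"), instr0)
  expect_equal(a$raw[["DD"]], 0)
})

test_that("kinetic series draws species by the two-state law", {
  instr <- default_instr
  # limit: k -> infinity, any t > 0 gives the equilibrium fraction
  mix <- mixture_time_course(f0 = 0, f_inf = 1, k_obs = 1e9,
                             donor_only_fraction = 0, times = c(0.5))
  sim <- simulate_kinetic_series(mix, instr, bursts_per_timepoint = 300,
                                 timestamps = FALSE, seed = 4)
  expect_equal(sim$truth$n_decompacted, 300)

  # at t = 0 the decompacted share is f0 within binomial error
  mix0 <- mixture_time_course(f0 = 0.1, f_inf = 0.9, k_obs = 0.5,
                              donor_only_fraction = 0, times = c(0))
  sim0 <- simulate_kinetic_series(mix0, instr, bursts_per_timepoint = 4000,
                                  timestamps = FALSE, seed = 5)
  p <- sim0$truth$n_decompacted / 4000
  expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))

  # half-life: t = ln2 / k gives share 0.5 within 3 binomial sigma
  mixh <- mixture_time_course(f0 = 0.1, f_inf = 0.9, k_obs = 0.5,
                              donor_only_fraction = 0,
                              times = c(log(2) / 0.5))
  simh <- simulate_kinetic_series(mixh, instr, bursts_per_timepoint = 4000,
                                  timestamps = FALSE, seed = 6)
  ph <- simh$truth$n_decompacted / 4000
  expect_lt(abs(ph - 0.5), 3 * sqrt(0.25 / 4000))

  expect_error(simulate_kinetic_series(mixh, instr,
                                       bursts_per_timepoint = 0),
               "bursts_per_timepoint")
})

test_that("fixed seed gives bit-identical streams and every microtime is in one PIE window", {
  instr <- default_instr
  mix <- mixture_time_course(times = c(0.1, 1))
  s1 <- simulate_kinetic_series(mix, instr, bursts_per_timepoint = 200,
                                seed = 42)
  s2 <- simulate_kinetic_series(mix, instr, bursts_per_timepoint = 200,
                                seed = 42)
  expect_identical(as.data.frame(s1$streams[[1]]),
                   as.data.frame(s2$streams[[1]]))
  expect_identical(as.data.frame(s1$streams[[2]]),
                   as.data.frame(s2$streams[[2]]))
  for (st in s1$streams) {
    expect_true(all(st$microtime_ns >= 0 &
                      st$microtime_ns < instr$pie_period))
    expect_error(classify_pie(st$microtime_ns, instr), NA)
  }
})

test_that("distortion-free single-species mean E converges to truth within 3 SE", {
  instr0 <- instrument_spec(background_rates = c(D = 0, A = 0),
                            leakage_alpha = 0,
                            direct_excitation_delta = 0, gamma = 1)
  for (E in c(0.36, 0.053)) {
    pts <- sim_species_points(E, n = 10000, seed = round(100 * E),
                              instrument = instr0)
    se <- stats::sd(pts$E) / sqrt(nrow(pts))
    expect_lt(abs(mean(pts$E) - E), 3 * se)
  }
})

test_that("slow traces have ~1000 detected bursts per minute and law-abiding fractions", {
  instr <- default_instr
  mix <- mixture_time_course(k_obs = 0, f0 = 0.3, f_inf = 0.3,
                             donor_only_fraction = 0)
  trace <- simulate_slow_trace(mix, instr, duration = 180, seed = 9)
  seg <- segment_trace(trace, window = 60, instrument = instr)
  expect_length(seg$bursts, 3)
  n_per_win <- vapply(seg$bursts, nrow, integer(1))
  # ~1000 arrivals/window; small bursts fall below the detection threshold
  expect_true(all(n_per_win > 650 & n_per_win < 1150))
  # k = 0: constant composition across windows (binomial error)
  corr <- correction_set_from_instrument(instr)
  frac_high <- vapply(seg$bursts, function(b) {
    g <- gate_stoichiometry(fret_points(b, corr))
    mean(g$E > 0.2)
  }, numeric(1))
  expect_lt(max(frac_high) - min(frac_high),
            6 * sqrt(0.7 * 0.3 / min(n_per_win)))
})

test_that("slow-trace window fractions follow the two-state law for known parameters", {
  instr <- default_instr
  mix <- mixture_time_course(k_obs = 0.01, f0 = 0.1, f_inf = 0.9,
                             donor_only_fraction = 0)
  trace <- simulate_slow_trace(mix, instr, duration = 240, t_start = 5,
                               seed = 10)
  truth <- ground_truth(trace)
  expect_false(is.null(truth))
  seg <- segment_trace(trace, window = 60, instrument = instr)
  corr <- correction_set_from_instrument(instr)
  for (k in seq_along(seg$bursts)) {
    g <- gate_stoichiometry(fret_points(seg$bursts[[k]], corr))
    f_emp <- mean(g$E < 0.2)
    f_law <- two_state_fraction(5 + seg$midpoints[k], 0.01, 0.1, 0.9)
    expect_lt(abs(f_emp - f_law), 4 * sqrt(0.25 / nrow(g)) + 0.02)
  }
})
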