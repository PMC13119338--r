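test_that("channel positions map linearly to reaction times", {
  m <- timepoint_map(droplet_velocity = 0.6, dead_time = 0)
  expect_equal(position_to_time(m, 0.36), 0.6)
  expect_equal(position_to_time(m, 0), 0)
  # channel end: 36 mm at 0.6 mm/s is the ~60 s limit of the device
  expect_equal(position_to_time(m, 36), 60)
  md <- timepoint_map(dead_time = 0.25)
  expect_equal(position_to_time(md, 0), 0.25)
  expect_error(position_to_time(m, -1), "position")
  expect_error(timepoint_map(positions = c(1, 1)), "increasing")
})

test_that("two-state relaxation has the right limits and bounds", {
  expect_equal(two_state_fraction(0, 0.42, 0.1, 0.9), 0.1)
  expect_equal(two_state_fraction(1e9, 0.42, 0.1, 0.9), 0.9)
  expect_equal(two_state_fraction(1 / 0.42, 0.42, 0, 1), 1 - exp(-1))
  # monotone and bounded between f0 and f_inf
  t <- seq(0, 50, length.out = 200)
  f <- two_state_fraction(t, 0.3, 0.2, 0.8)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0.2 - 1e-12 & f <= 0.8 + 1e-12))
  fd <- two_state_fraction(t, 0.3, 0.9, 0.1)
  expect_true(all(diff(fd) < 0))
})

test_that("noiseless kinetic series are recovered exactly", {
  t <- 10^seq(-2, log10(20), length.out = 8)
  f <- two_state_fraction(t, 0.42, 0.1, 0.9)
  fit <- fit_kinetics(t, f)
  expect_equal(unname(fit$estimate),
               c(0.42, 0.1, 0.9), tolerance = 1e-6)
  # invariance to time-point order
  o <- c(5, 1, 8, 3, 7, 2, 6, 4)
  fit2 <- fit_kinetics(t[o], f[o])
  expect_equal(fit2$estimate, fit$estimate, tolerance = 1e-9)
  # constant series: flat flag with k = 0
  flat <- fit_kinetics(t, rep(0.4, 8))
  expect_true(flat$flat)
  expect_equal(flat$estimate[["k_obs"]], 0)
  expect_error(fit_kinetics(c(1, 2, 3), c(0.1, 0.2, 0.3)), "4 time points")
})

test_that("trace segmentation drops partial windows and errors when too short", {
  instr <- default_instr
  mix <- mixture_time_course(k_obs = 0, donor_only_fraction = 0)
  short <- simulate_slow_trace(mix, instr, duration = 59, seed = 3)
  expect_error(segment_trace(short, window = 60, instrument = instr),
               "shorter")
  tr <- simulate_slow_trace(mix, instr, duration = 150, seed = 3)
  expect_message(seg <- segment_trace(tr, window = 60, instrument = instr),
                 "partial")
  expect_length(seg$bursts, 2)
  expect_equal(seg$midpoints, c(30, 90))
})

test_that("condition tables are long-format with one row per fit", {
  t <- c(0.1, 0.5, 2, 8)
  mk <- function(k, len, conc) {
    fit_kinetics(t, two_state_fraction(t, k, 0.1, 0.8),
                 condition = list(par_length = len, par_conc_nM = conc,
                                  ionic_strength_mM = 300))
  }
  tab <- summarize_conditions(list(mk(0.4, "28-30", 240),
                                   mk(0.5, "28-30", 480)))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$par_conc_nM, c(240, 480))
  expect_equal(tab$k_obs, c(0.4, 0.5), tolerance = 1e-6)
  expect_equal(nrow(summarize_conditions(list())), 0)
  # two-regime contrast survives the summary table
  fast <- mk(0.4, "28-30", 240)
  slow <- mk(0.004, "7", 240)
  tab2 <- summarize_conditions(list(fast, slow))
  expect_equal(tab2$k_obs[1] / tab2$k_obs[2], 100, tolerance = 1e-4)
})

test_that("counts-level pipeline recovers the generator rate within its CI", {
  instr <- default_instr
  mix <- mixture_time_course(k_obs = 0.42, f0 = 0.2, f_inf = 0.9)
  sim <- simulate_kinetic_series(mix, instr, bursts_per_timepoint = 3000,
                                 timestamps = FALSE, seed = 101)
  ana <- analyze_droplet_series(sim$bursts, sim$times, instrument = instr)
  ci <- ana$kinetic_fit$ci["k_obs", ]
  expect_lt(abs(ana$kinetic_fit$estimate[["k_obs"]] - 0.42), 0.1)
  expect_true(ci["lower"] <= 0.42 * 1.2 && ci["upper"] >= 0.42 * 0.8)
})
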