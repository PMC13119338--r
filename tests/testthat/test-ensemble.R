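test_that("Förster relation and its algebraic identity", {
  expect_equal(forster_efficiency(5.4), 0.5)
  expect_equal(forster_efficiency(1e-9), 1, tolerance = 1e-9)
  expect_equal(forster_efficiency(10.8), 1 / 65)
  expect_error(forster_efficiency(0), "positive")
  # E(r) * (1 + (r/R0)^6) = 1 for all r; strictly decreasing
  r <- withr::with_seed(1, runif(1000, 0.5, 20))
  expect_equal(forster_efficiency(r) * (1 + (r / 5.4)^6), rep(1, 1000),
               tolerance = 1e-12)
  rs <- sort(r)
  expect_true(all(diff(forster_efficiency(rs)) < 0))
})

test_that("mean efficiency is the ensemble average of E", {
  expect_equal(mean_efficiency(rep(5.4, 10)), 0.5)
  expect_equal(mean_efficiency(c(1e-9, 1e9)), 0.5, tolerance = 1e-9)
  expect_equal(mean_efficiency(c(5.4, 10.8)), (0.5 + 1 / 65) / 2)
  expect_error(mean_efficiency(numeric(0)), "empty")
  # Jensen: for convex E(r) regions the ensemble mean exceeds E(mean r);
  # checked against a dense-quadrature oracle on lognormal distances
  qs <- stats::qlnorm(seq(1e-4, 1 - 1e-4, length.out = 20001),
                      meanlog = log(8), sdlog = 0.25)
  oracle <- mean(forster_efficiency(qs))
  samp <- withr::with_seed(4, stats::rlnorm(2e5, log(8), 0.25))
  expect_equal(mean_efficiency(samp), oracle, tolerance = 2e-3)
  expect_gt(oracle, forster_efficiency(mean(qs))) # convex side of R0
})

test_that("contact counting matches an exhaustive pairwise oracle", {
  expect_equal(count_contacts(matrix(c(0, 0, 0), 1),
                              matrix(c(1, 0, 0), 1)), 1)
  expect_equal(count_contacts(matrix(c(0, 0, 0), 1),
                              matrix(c(1.3, 0, 0), 1)), 0)
  expect_equal(count_contacts(matrix(numeric(0), 0, 3),
                              matrix(c(1, 1, 1), 1)), 0L)
  for (rep in 1:5) {
    A <- withr::with_seed(rep, matrix(runif(60, 0, 4), 20, 3))
    B <- withr::with_seed(rep + 100, matrix(runif(60, 0, 4), 20, 3))
    brute <- 0L
    for (i in 1:20) for (j in 1:20)
      if (sqrt(sum((A[i, ] - B[j, ])^2)) < 1.2) brute <- brute + 1L
    expect_equal(count_contacts(A, B, 1.2), brute)
  }
})

test_that("contact lifetimes average maximal runs, boundaries included", {
  expect_equal(contact_lifetime(c(TRUE, TRUE, FALSE, TRUE), 1), 1.5)
  nc <- contact_lifetime(c(FALSE, FALSE), 1)
  expect_equal(as.numeric(nc), 0)
  expect_true(attr(nc, "no_contacts"))
  expect_equal(contact_lifetime(rep(TRUE, 5), 0.2), 1)
  for (rep in 1:5) {
    x <- withr::with_seed(rep, runif(200) < 0.4)
    r <- rle(x)
    oracle <- mean(r$lengths[r$values]) * 0.02
    expect_equal(contact_lifetime(x, 0.02), oracle)
  }
})

test_that("WHAM reassembles biased windows into the unbiased PMF", {
  kT <- 0.008314462618 * 300
  k0 <- 2; x0 <- 8; kb <- 10
  centers <- seq(0, 16, length.out = 16)
  windows <- withr::with_seed(6, lapply(centers, function(c0) {
    v <- kT / (k0 + kb)
    m <- (k0 * x0 + kb * c0) / (k0 + kb)
    umbrella_window(c0, rnorm(4000, m, sqrt(v)), force_constant = kb)
  }))
  pmf <- wham_pmf(windows, n_bins = 150)
  truth <- 0.5 * k0 * (pmf$x - x0)^2
  well <- pmf$n > 500 & abs(pmf$x - x0) < 5
  diff <- pmf$pmf[well] - truth[well]
  diff <- diff - mean(diff) # PMFs agree up to an additive constant
  expect_lt(max(abs(diff)), 0.5)
  # invariance to window order (up to the constant)
  pmf2 <- wham_pmf(windows[withr::with_seed(7, sample(16))],
                   n_bins = 150)
  d <- pmf2$pmf - pmf$pmf
  expect_lt(max(abs(d - mean(d, na.rm = TRUE)), na.rm = TRUE), 1e-4)
})

test_that("WHAM handles flat data and rejects non-overlapping windows", {
  flat <- withr::with_seed(8, lapply(c(3, 6), function(c0)
    umbrella_window(c0, runif(20000, 0, 10), force_constant = 1e-6)))
  pmf <- wham_pmf(flat, n_bins = 30)
  mid <- pmf$pmf[pmf$x > 1 & pmf$x < 9]
  expect_lt(max(mid) - min(mid), 0.2 * 0.008314462618 * 300) # << kT
  apart <- withr::with_seed(9, lapply(c(0, 100), function(c0)
    umbrella_window(c0, rnorm(100, c0, 0.2))))
  expect_error(wham_pmf(apart), "overlap")
})
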