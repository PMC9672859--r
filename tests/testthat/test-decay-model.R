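# Forward decay model: pure exponentials, IRF convolution, composition.

test_that("pure decay matches analytic values", {
  # identity at the origin
  expect_equal(pure_decay(0, decay_model(1, 1))$expected, 1.0)
  # analytic plug-in
  expect_equal(pure_decay(2, decay_model(2, 2))$expected, 2 * exp(-1))
  # sum-of-parts oracle: evaluate each component independently, then sum
  two <- decay_model(c(1, 1), c(0.5, 3))
  t <- 1
  parts <- pure_decay(t, decay_model(1, 0.5))$expected +
    pure_decay(t, decay_model(1, 3))$expected
  expect_equal(pure_decay(t, two)$expected, parts)
  expect_equal(pure_decay(t, two)$expected, exp(-2) + exp(-1 / 3))
  # zero before the origin, strictly decreasing after
  v <- pure_decay(seq(0, 10, by = 0.1), decay_model(1, 2), t0 = 1)$expected
  expect_true(all(v[seq(0, 10, by = 0.1) < 1] == 0))
  after <- v[seq(0, 10, by = 0.1) >= 1]
  expect_true(all(diff(after) < 0))
})

test_that("invalid grids and parameters are rejected", {
  expect_error(pure_decay(c(0, 1, 3), decay_model(1, 1)),
               class = "flimr_invalid_grid")
  expect_error(decay_model(1, -1), class = "flimr_invalid_parameter")
  expect_error(decay_model(-1, 1), class = "flimr_invalid_parameter")
  expect_error(decay_model(c(1, 1, 1), c(1, 2, 3)),
               class = "flimr_invalid_parameter")
  expect_error(gaussian_irf(1, 0), class = "flimr_invalid_parameter")
})

test_that("near-delta IRF leaves the decay unchanged", {
  tt <- make_grid(512, 12.5)
  dt <- tt[2] - tt[1]
  dec <- pure_decay(tt, decay_model(100, 2.0), t0 = tt[1])
  out <- convolve_irf(dec, gaussian_irf(mu = tt[1], sigma = dt / 100))
  sel <- dec$expected > max(dec$expected) * 1e-9
  expect_lt(max(abs(out$expected[sel] - dec$expected[sel]) /
                  dec$expected[sel]), 1e-3)
})

test_that("FFT convolution matches the O(N^2) direct loop", {
  tt <- make_grid(128, 12.5)
  dec <- pure_decay(tt, decay_model(c(50, 100), c(0.4, 2.8)), t0 = tt[1])
  irf <- gaussian_irf(mu = 1.0, sigma = 0.2)
  k <- flimr:::irf_kernel(irf, tt)
  direct <- conv_direct(dec$expected, k)
  out <- convolve_irf(dec, irf)$expected
  expect_lt(max(abs(out - direct)) / max(direct), 1e-9)
})

test_that("convolution agrees with the exponentially modified Gaussian", {
  # fine binning; relative agreement where the curve carries real mass
  tt <- make_grid(32768, 12.5)
  for (tau in c(0.3, 2.5)) {
    for (sigma in c(0.1, 0.3)) {
      m <- decay_model(100, tau, irf = gaussian_irf(2.0, sigma))
      fftc <- model_curve(tt, m)$expected
      emg <- emg_curve(tt, 100, tau, 2.0, sigma)
      sel <- emg > max(emg) * 1e-3
      expect_lt(max(abs(fftc[sel] - emg[sel]) / emg[sel]), 1e-4)
    }
  }
})

test_that("convolution is linear and conserves counts", {
  tt <- make_grid(256, 12.5)
  irf <- gaussian_irf(1.0, 0.15)
  # lifetimes short enough that the decayed signal lies inside the grid,
  # the precondition for count conservation under truncated convolution
  d1 <- pure_decay(tt, decay_model(80, 0.4), t0 = tt[1])
  d2 <- pure_decay(tt, decay_model(40, 0.6), t0 = tt[1])
  lin <- tibble::tibble(time_ns = tt,
                        expected = 2 * d1$expected + 3 * d2$expected)
  lhs <- convolve_irf(lin, irf)$expected
  rhs <- 2 * convolve_irf(d1, irf)$expected + 3 * convolve_irf(d2, irf)$expected
  expect_lt(max(abs(lhs - rhs)), 1e-12 * max(rhs))
  # conservation: decay fully inside the grid (short lifetimes), IRF interior
  total_in <- sum(lin$expected)
  expect_lt(abs(sum(lhs) - total_in) / total_in, 1e-6)
})

test_that("model_curve composes decay and IRF correctly", {
  tt <- make_grid(256, 12.5)
  # zero-amplitude components give an all-zero curve
  z <- model_curve(tt, decay_model(c(0, 0), c(0.4, 2.8),
                                   irf = gaussian_irf(1, 0.1)))
  expect_true(all(z$expected == 0))
  # tail mode is exactly the pure decay
  mt <- decay_model(10, 2, t0 = 1.5)
  expect_equal(model_curve(tt, mt), pure_decay(tt, mt, t0 = 1.5))
  # bi convolution curve = sum of the two separately convolved mono curves
  irf <- gaussian_irf(1.0, 0.12)
  bi <- model_curve(tt, decay_model(c(30, 70), c(0.4, 2.8), irf = irf))$expected
  mono_sum <- model_curve(tt, decay_model(30, 0.4, irf = irf))$expected +
    model_curve(tt, decay_model(70, 2.8, irf = irf))$expected
  expect_lt(max(abs(bi - mono_sum)), 1e-12 * max(bi))
})

test_that("model curve is non-increasing well past the IRF", {
  tt <- make_grid(500, 12.5)
  m <- decay_model(c(20, 100), c(0.4, 2.8), irf = gaussian_irf(1.0, 0.15))
  cv <- model_curve(tt, m)$expected
  tail_sel <- tt > 1.0 + 5 * 0.15
  expect_true(all(diff(cv[tail_sel]) <= 1e-12))
})

test_that("measured IRF must share the decay grid", {
  tt <- make_grid(128, 12.5)
  irf_hist <- tibble::tibble(time_ns = make_grid(64, 12.5),
                             counts = stats::dnorm(make_grid(64, 12.5), 1, 0.1))
  mi <- measured_irf(irf_hist)
  expect_equal(sum(mi$histogram$response), 1.0)
  dec <- pure_decay(tt, decay_model(10, 2), t0 = tt[1])
  expect_error(convolve_irf(dec, mi), class = "flimr_grid_mismatch")
  # on a matching grid, a measured Gaussian IRF reproduces the parametric one
  irf_match <- measured_irf(tibble::tibble(
    time_ns = tt, counts = stats::dnorm(tt, 1, 0.1)))
  a <- convolve_irf(dec, irf_match)$expected
  b <- convolve_irf(dec, gaussian_irf(1, 0.1))$expected
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("periodic model equals the wrapped sum of pulse responses", {
  # geometric wrap identity: periodic curve at the grid equals the linear
  # convolution of the infinite pulse train, computed here by explicit
  # summation over previous pulses on an extended grid
  n <- 250
  tt <- make_grid(n, 12.5)
  dt <- tt[2] - tt[1]
  m <- decay_model(100, 2.8, irf = gaussian_irf(1.0, 0.1))
  per <- model_curve(tt, m, periodic = TRUE)$expected
  # oracle: evaluate the single-pulse curve on a 5x longer grid and fold
  big <- (seq_len(5 * n) - 0.5) * dt
  lin <- model_curve(big, m)$expected
  folded <- rowSums(matrix(lin, nrow = n))
  expect_lt(max(abs(per - folded)) / max(folded), 1e-3)
})
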