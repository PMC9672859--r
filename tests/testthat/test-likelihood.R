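# Poisson NLL, maximum-likelihood fitting, model-order selection.

test_that("poisson_nll matches the formula", {
  expect_equal(poisson_nll(1, 1), 1.0)
  # direct hand evaluation: (2 + 1) - (1*ln 2 + 2*ln 1)
  expect_equal(poisson_nll(c(2, 1), c(1, 2)), 3 - log(2))
  expect_error(poisson_nll(c(1, 2), 1), class = "flimr_numeric_domain")
  expect_error(poisson_nll(-1, 1), class = "flimr_numeric_domain")
  expect_error(poisson_nll(1, -1), class = "flimr_numeric_domain")
  expect_error(poisson_nll(1, 1.5), class = "flimr_numeric_domain")
})

test_that("per-bin NLL is minimised when expected equals observed", {
  obs <- c(5, 3, 2, 1, 8)
  base <- poisson_nll(obs, obs)
  # brute-force perturbation around the candidate minimiser
  for (i in seq_along(obs)) {
    for (eps in c(-0.3, -0.1, 0.1, 0.3)) {
      pert <- obs
      pert[i] <- pert[i] + eps
      expect_gt(poisson_nll(pert, obs), base)
    }
  }
})

test_that("noiseless curves are recovered almost exactly", {
  tt <- make_grid(250, 12.5)
  truth <- decay_model(800, 2.2, irf = gaussian_irf(1.0, 0.12))
  counts <- round(model_curve(tt, truth)$expected)
  hist <- tibble::tibble(time_ns = tt, counts = counts)
  fit <- fit_decay(hist, fit_config(model_order = "mono", endpoint = "full",
                                    periodic = FALSE))
  expect_true(fit$converged)
  expect_lt(abs(fit$signal_lifetime - 2.2) / 2.2, 1e-3)
  expect_lt(abs(fit$mu - 1.0), 0.01)
})

test_that("Poisson-sampled mono decay is recovered within 2 percent", {
  truth <- mono_truth(n_photons = 1e5)
  hist <- simulate_decay(truth, seed = 11)
  fit <- fit_decay(hist, fit_config(model_order = "mono", endpoint = "full"))
  expect_true(fit$converged)
  expect_lt(abs(fit$signal_lifetime - 2.5) / 2.5, 0.02)
})

test_that("a bi fit of signal-free data gives a negligible signal fraction", {
  # all photons in the fast component. With both lifetimes anchored the
  # amplitude split is identifiable and the signal amplitude must vanish;
  # with the lifetimes free, two equal fitted lifetimes make the split
  # arbitrary, which is exactly why assess_model_order() enforces a
  # minimum lifetime separation.
  truth <- simulation_truth(tau_signal = 2.8, tau_auto = 0.4,
                            fraction_auto = 1, n_photons = 5e4, sigma = 0.1)
  hist <- simulate_decay(truth, seed = 12)
  fit <- fit_decay(hist, fit_config(model_order = "bi", endpoint = "full",
                                    fixed = list(tau_auto = 0.4,
                                                 tau_signal = 2.8)))
  expect_lt(fit$amplitude_fractions[["signal"]], 1e-3)
})

test_that("low-count data raises a low-counts error", {
  hist <- tibble::tibble(time_ns = make_grid(64), counts = rep(1L, 64))
  expect_error(fit_decay(hist, fit_config(min_counts = 100)),
               class = "flimr_low_counts")
})

test_that("frozen parameters pass through bit-identically", {
  truth <- simulation_truth(tau_signal = 2.2, tau_auto = 0.4,
                            fraction_auto = 0.3, n_photons = 2e4)
  hist <- simulate_decay(truth, seed = 13)
  frozen <- list(tau_auto = 0.412345678901234, mu = 1.00123456789,
                 sigma = 0.0987654321)
  fit <- fit_decay(hist, fit_config(model_order = "bi", endpoint = "full",
                                    fixed = frozen))
  expect_identical(unname(fit$params[["tau_auto"]]), frozen$tau_auto)
  expect_identical(unname(fit$params[["mu"]]), frozen$mu)
  expect_identical(unname(fit$params[["sigma"]]), frozen$sigma)
  expect_error(
    fit_decay(hist, fit_config(model_order = "mono", endpoint = "full",
                               fixed = list(not_a_param = 1))),
    class = "flimr_invalid_parameter"
  )
})

test_that("identical inputs give bit-identical fits", {
  hist <- simulate_decay(mono_truth(), seed = 14)
  cfg <- fit_config(model_order = "mono")
  f1 <- fit_decay(hist, cfg)
  f2 <- fit_decay(hist, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$n_bins_used, f2$n_bins_used)
})

test_that("the fitted likelihood dominates the truth parameters", {
  truth <- mono_truth(n_photons = 2e4)
  hist <- simulate_decay(truth, seed = 15)
  fit <- fit_decay(hist, fit_config(model_order = "mono", endpoint = "full"))
  u <- hist$time_ns - hist$time_ns[1]
  amp <- 1e4 / sum(exp(-u / 2.5))
  obj <- flimr:::make_objective(hist$time_ns, hist$counts, nrow(hist),
                                "convolution", "mono", list())
  nll_truth <- obj$nll(c(amp_signal = amp, tau_signal = 2.5,
                         mu = 1.0, sigma = 0.1))
  expect_lte(fit$nll, nll_truth)
})

test_that("estimator error shrinks as photons grow", {
  errs <- sapply(c(1e3, 1e4, 1e5), function(np) {
    e <- sapply(1:6, function(s) {
      h <- simulate_decay(mono_truth(n_photons = np), seed = 20 + s)
      f <- fit_decay(h, fit_config(model_order = "mono", endpoint = "full"))
      abs(f$signal_lifetime - 2.5) / 2.5
    })
    stats::median(e)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2], 0.03)
})

test_that("tail fitting recovers a pure exponential", {
  set.seed(31)
  times <- stats::rexp(2e4, rate = 1 / 2.0)
  hist <- bin_photons(times, n_bins = 250, window = 25)
  fit <- fit_decay(hist, fit_config(mode = "tail", model_order = "mono",
                                    endpoint = "full", tail_start = 0.5))
  expect_lt(abs(fit$signal_lifetime - 2.0) / 2.0, 0.02)
  expect_true(is.na(fit$mu))
})

test_that("model order selection obeys the three-condition rule", {
  # simulated mono data chooses mono
  h_mono <- simulate_decay(mono_truth(n_photons = 1e5, tau = 2.0), seed = 41)
  f1 <- fit_decay(h_mono, fit_config(model_order = "auto", endpoint = "full"))
  expect_identical(f1$model_order, "mono")
  # simulated bi data chooses bi
  h_bi <- simulate_decay(
    simulation_truth(tau_signal = 2.8, tau_auto = 0.4, fraction_auto = 0.3,
                     n_photons = 1e5),
    seed = 42
  )
  f2 <- fit_decay(h_bi, fit_config(model_order = "auto", endpoint = "full"))
  expect_identical(f2$model_order, "bi")
  expect_gte(f2$signal_lifetime, f2$auto_lifetime)
})

test_that("collapsed or tiny components force mono", {
  stub <- function(nll, npar, tau_auto, tau_signal, fr_auto, conv = TRUE) {
    structure(list(nll = nll, npar = npar, n_bins_used = 200L,
                   n_points_used = 200L, converged = conv,
                   signal_lifetime = tau_signal, auto_lifetime = tau_auto,
                   amplitude_fractions = c(auto = fr_auto,
                                           signal = 1 - fr_auto)),
              class = "flim_fit")
  }
  mono <- stub(-1000, 4L, NA, 2.0, 0)
  # equal lifetimes: separation rule forces mono even with a huge NLL gain
  expect_identical(assess_model_order(stub(-1200, 6L, 2.0, 2.0, 0.5), mono),
                   "mono")
  # vanishing amplitude fraction forces mono
  expect_identical(assess_model_order(stub(-1200, 6L, 0.4, 2.0, 0.001), mono),
                   "mono")
  # no BIC advantage forces mono
  expect_identical(assess_model_order(stub(-1001, 6L, 0.4, 2.0, 0.3), mono),
                   "mono")
  # clear two-component evidence keeps bi
  expect_identical(assess_model_order(stub(-1200, 6L, 0.4, 2.0, 0.3), mono),
                   "bi")
  # unconverged fits fall back to the converged one
  expect_identical(
    assess_model_order(stub(-1200, 6L, 0.4, 2.0, 0.3, conv = FALSE), mono),
    "mono"
  )
  expect_error(
    assess_model_order(stub(-1200, 6L, 0.4, 2.0, 0.3, conv = FALSE),
                       stub(-1000, 4L, NA, 2.0, 0, conv = FALSE)),
    class = "flimr_fit_failure"
  )
})

test_that("tidy and glance expose the fit", {
  hist <- simulate_decay(mono_truth(), seed = 16)
  fit <- fit_decay(hist, fit_config(model_order = "mono", endpoint = "full"))
  td <- tidy(fit)
  expect_setequal(td$term, c("amp_signal", "tau_signal", "mu", "sigma"))
  g <- glance(fit)
  expect_equal(g$tau_signal_ns, fit$signal_lifetime)
  expect_true(g$converged)
  fv <- fitted(fit)
  expect_equal(nrow(fv), fit$n_bins_used)
  # fitted curve reproduces the optimiser's NLL
  expect_equal(poisson_nll(fv$expected, hist$counts[seq_len(nrow(fv))]),
               fit$nll, tolerance = 1e-8)
})
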