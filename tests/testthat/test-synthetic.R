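# Monte-Carlo TCSPC/FLIM generator: distributional checks, determinism,
# conservation, scene construction.

test_that("pure background sampling is uniform over the window", {
  truth <- simulation_truth(background_fraction = 1, fraction_auto = 0,
                            n_photons = 1e5)
  t <- sample_photons(truth, seed = 1)
  ks <- suppressWarnings(
    stats::ks.test(t, "punif", min = 0, max = truth$window))
  expect_lt(unname(ks$statistic), 0.02)
  expect_true(all(t >= 0 & t < truth$window))
})

test_that("jitter-free sampling has the exponential mean", {
  # wide window so wrap-around is negligible
  truth <- simulation_truth(tau_signal = 2.0, fraction_auto = 0,
                            mu = 1.0, sigma = 1e-6, n_photons = 5e4,
                            window = 60, n_bins = 1200)
  t <- sample_photons(truth, seed = 2)
  se <- 2.0 / sqrt(length(t))
  expect_lt(abs(mean(t) - 1.0 - 2.0), 2 * se)
})

test_that("sampling is reproducible and leaves the RNG state alone", {
  truth <- simulation_truth(n_photons = 1000)
  a <- sample_photons(truth, seed = 3)
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  b <- sample_photons(truth, seed = 3)
  after <- stats::runif(1)
  expect_identical(a, b)
  expect_identical(before, after)
})

test_that("binning conserves photons and agrees with a recount loop", {
  truth <- simulation_truth(n_photons = 5000)
  t <- sample_photons(truth, seed = 4)
  h <- bin_photons(t, truth)
  expect_identical(sum(h$counts), length(t))
  # one photon at a bin centre
  single <- bin_photons(6.125, n_bins = 250, window = 12.5)
  expect_equal(sum(single$counts), 1L)
  expect_equal(single$counts[single$time_ns == 6.125], 1L)
  # independent sort-and-count loop
  dt <- truth$window / truth$n_bins
  manual <- integer(truth$n_bins)
  for (x in t) {
    b <- floor(x / dt) + 1
    if (b >= 1 && b <= truth$n_bins) manual[b] <- manual[b] + 1L
  }
  expect_identical(h$counts, manual)
})

test_that("invalid truths are rejected", {
  expect_error(simulation_truth(tau_signal = -1),
               class = "flimr_invalid_parameter")
  expect_error(simulation_truth(fraction_auto = 0.7, background_fraction = 0.5),
               class = "flimr_invalid_parameter")
  expect_error(sample_photons(simulation_truth(), n = 0),
               class = "flimr_invalid_parameter")
})

test_that("scenes place photons inside their ROIs and conserve budgets", {
  rois <- tibble::tibble(
    label = 1L, center_row = 20, center_col = 20, semi_major = 10,
    semi_minor = 6, orientation = 0.3, thickness = 3, n_photons = 4000L
  )
  scene <- scene_config(c(40, 40), rois, n_timepoints = 6L)
  sim <- simulate_scene(scene, seed = 5)
  expect_length(sim$images, 6L)
  # all photons on ring pixels (zero field background)
  total <- sum_flim_images(sim$images)
  per_pixel <- apply(total$counts, c(1, 2), sum)
  expect_true(all(per_pixel[sim$mask == 0L] == 0L))
  # budget conserved exactly across timepoints
  expect_identical(sum(total$counts), 4000L)
  per_tp <- sapply(sim$images, function(im) sum(im$counts))
  expect_true(max(per_tp) - min(per_tp) <= 1)
  # rerun with the same seed is identical
  sim2 <- simulate_scene(scene, seed = 5)
  expect_identical(sim$images[[1]]$counts, sim2$images[[1]]$counts)
  expect_identical(sim$mask, sim2$mask)
})

test_that("overlapping ROIs are a configuration error", {
  rois <- tibble::tibble(
    label = 1:2, center_row = c(20, 22), center_col = c(20, 22),
    semi_major = 10, semi_minor = 8, orientation = 0, thickness = 4,
    n_photons = 100L
  )
  expect_error(simulate_scene(scene_config(c(40, 40), rois), seed = 6),
               class = "flimr_config_error")
  expect_error(
    scene_config(c(40, 40), rois[, c("label", "center_row")]),
    class = "flimr_config_error"
  )
})

test_that("per-ROI empirical lifetimes match their truths", {
  # moment oracle: mean arrival minus mu estimates tau when only the signal
  # component is present and jitter is narrow
  scene <- gradient_scene(n_rings = 4, photons_per_ring = 1e4,
                          tau_range = c(2.0, 3.0), dims = c(64, 64),
                          base_truth = simulation_truth(fraction_auto = 0,
                                                        window = 50,
                                                        n_bins = 1000))
  sim <- simulate_scene(scene, seed = 7)
  segs <- attach_histograms(mask_segments(sim$mask), sim$images)
  for (i in seq_len(nrow(segs))) {
    h <- segs$histogram[[i]]
    tau_hat <- sum(h$time_ns * h$counts) / sum(h$counts) - 1.0
    tau_true <- sim$truth$tau_signal[sim$truth$label == segs$label[i]]
    expect_lt(abs(tau_hat - tau_true) / tau_true, 0.05)
  }
})

test_that("generated decays are recovered by the fitting stack", {
  # generative/fit consistency across a small truth lattice
  for (tau in c(1.5, 3.5)) {
    for (fa in c(0, 0.4)) {
      truth <- simulation_truth(tau_signal = tau, tau_auto = 0.4,
                                fraction_auto = fa, n_photons = 3e4)
      h <- simulate_decay(truth, seed = round(100 * tau + 10 * fa))
      order <- if (fa > 0) "bi" else "mono"
      f <- fit_decay(h, fit_config(model_order = order, endpoint = "full"))
      expect_true(f$converged)
      expect_lt(abs(f$signal_lifetime - tau) / tau, 0.08)
    }
  }
})
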