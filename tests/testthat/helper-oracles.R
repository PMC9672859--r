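# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (nested loops, direct formulas) so they are independent
# of the implementation paths they check.

# O(N^2) direct discrete linear convolution, truncated to length(x).
conv_direct <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(i)) {
      acc <- acc + k[j] * x[i - j + 1]
    }
    out[i] <- acc
  }
  out
}

# Uniform bin-centre grid over `window` ns.
make_grid <- function(n_bins = 250, window = 12.5) {
  (seq_len(n_bins) - 0.5) * (window / n_bins)
}

# Rasterized filled ellipse pixel mask (matrix), axes in px, orientation in
# radians from the row axis.
raster_ellipse <- function(rows, cols, cr, cc, a, b, theta = 0) {
  m <- matrix(0L, rows, cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      dr <- r - cr
      dc <- c - cc
      pu <- dr * cos(theta) + dc * sin(theta)
      pv <- -dr * sin(theta) + dc * cos(theta)
      if ((pu / a)^2 + (pv / b)^2 <= 1) m[r, c] <- 1L
    }
  }
  m
}

# Small deterministic photon-count cube for image tests.
random_cube <- function(rows, cols, nb, seed = 1, lambda = 0.3) {
  set.seed(seed)
  array(stats::rpois(rows * cols * nb, lambda), dim = c(rows, cols, nb))
}

# Default single-curve truth used across fitting tests.
mono_truth <- function(n_photons = 1e4, tau = 2.5, ...) {
  simulation_truth(tau_signal = tau, fraction_auto = 0, n_photons = n_photons,
                   sigma = 0.1, ...)
}
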