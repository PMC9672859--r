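# Forward model of a measured TCSPC decay: sums of exponentials convolved
# with an instrument response function (IRF).

#' Construct a decay model
#'
#' A decay model is one or two exponential components (amplitude in expected
#' counts per bin at the decay origin, lifetime in ns) plus an optional
#' instrument response. In two-component mode the shorter-lifetime component
#' is interpreted as autofluorescence and the longer one as sensor signal.
#'
#' @param amplitude Numeric vector of 1 or 2 non-negative amplitudes.
#' @param lifetime Numeric vector of matching positive lifetimes (ns).
#' @param irf An IRF created by [gaussian_irf()] or [measured_irf()], or
#'   `NULL` for tail mode (no convolution).
#' @param t0 Decay origin in ns. Required for tail mode; ignored in
#'   convolution mode, where the origin is fixed at the start of the grid and
#'   the IRF centre `mu` carries the time shift.
#' @return An object of class `decay_model`.
#' @examples
#' m <- decay_model(amplitude = c(1, 2), lifetime = c(0.4, 2.8),
#'                  irf = gaussian_irf(mu = 1, sigma = 0.1))
#' @export
decay_model <- function(amplitude, lifetime, irf = NULL, t0 = NULL) {
  if (length(amplitude) != length(lifetime) ||
      !length(amplitude) %in% 1:2) {
    abort_flimr("decay model needs 1 or 2 (amplitude, lifetime) pairs",
                "flimr_invalid_parameter")
  }
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    abort_flimr("amplitudes must be finite and >= 0", "flimr_invalid_parameter")
  }
  if (any(!is.finite(lifetime)) || any(lifetime <= 0)) {
    abort_flimr("lifetimes must be finite and > 0", "flimr_invalid_parameter")
  }
  ord <- order(lifetime)  # shorter lifetime first = autofluorescence
  structure(
    list(
      components = tibble::tibble(amplitude = amplitude[ord],
                                  lifetime = lifetime[ord]),
      irf = irf,
      t0 = t0
    ),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  n <- nrow(x$components)
  cat(sprintf("<decay_model: %s-exponential, %s>\n",
              if (n == 1L) "mono" else "bi",
              if (is.null(x$irf)) "tail mode" else paste0(x$irf$type, " IRF")))
  print(x$components)
  if (!is.null(x$irf) && x$irf$type == "gaussian") {
    cat(sprintf("IRF: mu = %.4g ns, sigma = %.4g ns\n", x$irf$mu, x$irf$sigma))
  }
  invisible(x)
}

#' Gaussian instrument response
#'
#' @param mu Pulse centre in ns.
#' @param sigma Width (standard deviation) in ns; must be positive.
#' @return An object of class `flim_irf` with `type = "gaussian"`.
#' @export
gaussian_irf <- function(mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) {
    abort_flimr("IRF sigma must be finite and > 0", "flimr_invalid_parameter")
  }
  structure(list(type = "gaussian", mu = mu, sigma = sigma), class = "flim_irf")
}

#' Measured instrument response
#'
#' Wraps a measured IRF histogram. The histogram is normalised to unit sum so
#' that convolution conserves total counts; it must share the time grid of the
#' decay it is applied to.
#'
#' @param histogram Data frame with columns `time_ns` and a value column
#'   (`counts` or `response`).
#' @return An object of class `flim_irf` with `type = "measured"`.
#' @export
measured_irf <- function(histogram) {
  cols <- decay_cols(histogram)
  validate_time_grid(cols$time_ns, min_bins = 2L)
  v <- cols$value
  if (any(v < 0) || sum(v) <= 0) {
    abort_flimr("measured IRF must be non-negative with positive total",
                "flimr_invalid_parameter")
  }
  structure(
    list(type = "measured",
         histogram = tibble::tibble(time_ns = cols$time_ns,
                                    response = v / sum(v))),
    class = "flim_irf"
  )
}

#' Evaluate a pure (unconvolved) exponential decay
#'
#' The value at time `t` is `sum_c A_c * exp(-(t - t0) / tau_c)` for
#' `t >= t0` and zero before the origin.
#'
#' @param times Numeric vector of times (ns), or a data frame with a
#'   `time_ns` column.
#' @param model A [decay_model()] (its IRF, if any, is ignored here), or a
#'   data frame with `amplitude` and `lifetime` columns.
#' @param t0 Decay origin in ns (default 0; a `t0` stored in the model takes
#'   precedence).
#' @return A tibble with columns `time_ns` and `expected`.
#' @export
pure_decay <- function(times, model, t0 = 0) {
  tt <- if (is.data.frame(times)) times[["time_ns"]] else times
  if (is.null(tt) || !is.numeric(tt)) {
    abort_flimr("`times` must be numeric or a data frame with `time_ns`",
                "flimr_invalid_grid")
  }
  validate_time_grid(tt, min_bins = 1L)
  comp <- if (inherits(model, "decay_model")) {
    if (!is.null(model$t0)) t0 <- model$t0
    model$components
  } else {
    model
  }
  if (any(comp$lifetime <= 0)) {
    abort_flimr("lifetimes must be > 0", "flimr_invalid_parameter")
  }
  v <- pure_decay_vec(tt, comp$amplitude, comp$lifetime, t0)
  tibble::tibble(time_ns = tt, expected = v)
}

# Bin-integrated exponential decay at offsets u (>= 0) from the origin:
# the exact integral of A*exp(-w/tau)*H(w) over [u - dt/2, u + dt/2],
# divided by dt. Equals the pointwise sample up to O((dt/tau)^2) away from
# the origin but treats the step at u = 0 exactly, which keeps the discrete
# convolution accurate at the rising edge (see the methods vignette).
bin_integrated_decay <- function(u, dt, amplitude, lifetime) {
  out <- numeric(length(u))
  for (c in seq_along(amplitude)) {
    tau <- lifetime[c]
    lo <- pmax(u - dt / 2, 0)
    out <- out + amplitude[c] * tau / dt *
      (exp(-lo / tau) - exp(-(u + dt / 2) / tau))
  }
  out
}

# Vectorised core shared with the fitting hot path.
pure_decay_vec <- function(times, amplitude, lifetime, t0) {
  u <- times - t0
  out <- numeric(length(times))
  live <- u >= 0
  for (c in seq_along(amplitude)) {
    out[live] <- out[live] + amplitude[c] * exp(-u[live] / lifetime[c])
  }
  out
}

# Discretize an IRF onto bin-centre times and normalize to unit sum.
irf_kernel <- function(irf, time_ns) {
  if (irf$type == "gaussian") {
    if (irf$mu < min(time_ns) - 0.5 * (time_ns[2] - time_ns[1]) ||
        irf$mu > max(time_ns) + 0.5 * (time_ns[2] - time_ns[1])) {
      abort_flimr("Gaussian IRF centre mu lies outside the time grid span",
                  "flimr_invalid_parameter")
    }
    k <- stats::dnorm(time_ns, mean = irf$mu, sd = irf$sigma)
    s <- sum(k)
    if (s <= 0) {
      abort_flimr("Gaussian IRF has no mass on the grid", "flimr_invalid_parameter")
    }
    k / s
  } else {
    ht <- irf$histogram$time_ns
    if (length(ht) != length(time_ns) ||
        any(abs(ht - time_ns) > 1e-9 * max(abs(time_ns), 1))) {
      abort_flimr("measured IRF grid does not match the decay grid",
                  "flimr_grid_mismatch")
    }
    irf$histogram$response
  }
}

# Linear (non-circular) convolution of x with unit-sum kernel k via FFT,
# zero-padded to the next power of two >= 2 * n, truncated to length(x).
convolve_linear <- function(x, k) {
  n <- length(x)
  m <- next_pow2(2L * n)
  xf <- stats::fft(c(x, numeric(m - n)))
  kf <- stats::fft(c(k, numeric(m - length(k))))
  out <- Re(stats::fft(xf * kf, inverse = TRUE)) / m
  pmax(out[seq_len(n)], 0)
}

#' Convolve a decay with an instrument response
#'
#' Discrete linear convolution on a uniform grid, computed by FFT with
#' zero-padding to the next power of two above twice the grid length so that
#' circular wrap-around cannot corrupt the rising edge. The IRF is
#' discretized at bin centres and normalised to unit sum, so total counts are
#' conserved whenever the IRF mass and decayed signal lie inside the grid.
#'
#' @param decay Data frame with `time_ns` and a value column, as returned by
#'   [pure_decay()].
#' @param irf A [gaussian_irf()] or [measured_irf()].
#' @return A tibble with columns `time_ns` and `expected`.
#' @export
convolve_irf <- function(decay, irf) {
  cols <- decay_cols(decay)
  validate_time_grid(cols$time_ns, min_bins = 8L)
  k <- irf_kernel(irf, cols$time_ns)
  tibble::tibble(time_ns = cols$time_ns,
                 expected = convolve_linear(cols$value, k))
}

#' Expected decay curve of a complete model
#'
#' In convolution mode the decay origin is fixed at the first grid time and
#' the pure decay is convolved with the model's IRF (whose centre `mu`
#' carries the pulse position). In tail mode (no IRF) the pure decay is
#' evaluated directly from the model's `t0`.
#'
#' @inheritParams pure_decay
#' @param model A [decay_model()].
#' @param periodic If `TRUE`, model repetition-rate wrap-around: the decay is
#'   geometrically summed over all previous excitation pulses and circularly
#'   convolved with the IRF over the grid span (the laser period). The
#'   default `FALSE` gives the single-pulse (zero-padded linear convolution)
#'   curve.
#' @return A tibble with columns `time_ns` and `expected`.
#' @export
model_curve <- function(times, model, periodic = FALSE) {
  tt <- if (is.data.frame(times)) times[["time_ns"]] else times
  if (is.null(model$irf)) {
    t0 <- model$t0 %||% 0
    return(pure_decay(tt, model, t0 = t0))
  }
  dt <- validate_time_grid(tt, min_bins = 8L)
  k <- irf_kernel(model$irf, tt)
  if (periodic) {
    n <- length(tt)
    d <- wrapped_decay_vec(tt - tt[1], dt, n * dt,
                           model$components$amplitude,
                           model$components$lifetime)
    out <- pmax(Re(stats::fft(stats::fft(d) * stats::fft(k),
                              inverse = TRUE)) / n, 0)
  } else {
    d <- bin_integrated_decay(tt - tt[1], dt, model$components$amplitude,
                              model$components$lifetime)
    out <- convolve_linear(d, k)
  }
  tibble::tibble(time_ns = tt, expected = out)
}

#' Closed-form mono-exponential decay convolved with a Gaussian IRF
#'
#' The exponentially modified Gaussian: for a decay `A * exp(-t/tau)` starting
#' at 0 convolved with a unit-area Gaussian centred at `mu` with width
#' `sigma`,
#' `f(t) = A * exp(sigma^2 / (2 tau^2) - (t - mu)/tau) * Phi((t - mu)/sigma - sigma/tau)`
#' where `Phi` is the standard normal CDF. Used as an independent analytic
#' check of the FFT convolution; not part of the fitting path.
#'
#' @param times Numeric times (ns).
#' @param amplitude,tau Decay amplitude and lifetime (ns).
#' @param mu,sigma Gaussian IRF centre and width (ns).
#' @return Numeric vector of expected values.
#' @export
emg_curve <- function(times, amplitude, tau, mu, sigma) {
  z <- (times - mu) / sigma - sigma / tau
  # log-space to avoid overflow of exp(sigma^2/(2 tau^2) - (t-mu)/tau)
  amplitude * exp(sigma^2 / (2 * tau^2) - (times - mu) / tau +
                    stats::pnorm(z, log.p = TRUE))
}
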