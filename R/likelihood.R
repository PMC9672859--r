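# Poisson maximum-likelihood estimation of decay parameters, with automatic
# endpoint selection and mono/bi model-order selection.

#' Poisson negative log-likelihood of a decay fit
#'
#' Computes `sum(m_i - n_i * log(m_i))` over bins, dropping the
#' parameter-independent `log(n_i!)` term. Expected values of zero are
#' floored at `eps` before the logarithm (observed counts can be nonzero in
#' bins where the model predicts almost nothing). Lower is better.
#'
#' @param expected Numeric vector of model-expected counts per bin.
#' @param observed Integer vector of observed counts per bin.
#' @param eps Floor applied to expected values before `log`.
#' @return Scalar negative log-likelihood (up to the dropped constant).
#' @export
poisson_nll <- function(expected, observed, eps = 1e-12) {
  if (length(expected) != length(observed)) {
    abort_flimr("expected and observed must have equal length", "flimr_numeric_domain")
  }
  if (any(!is.finite(expected)) || any(expected < 0)) {
    abort_flimr("expected counts must be finite and >= 0", "flimr_numeric_domain")
  }
  if (any(observed < 0) || any(observed != round(observed))) {
    abort_flimr("observed counts must be non-negative integers", "flimr_numeric_domain")
  }
  m <- pmax(expected, eps)
  sum(m - observed * log(m))
}

# NLL of the saturated model (expected = observed), used to turn the raw NLL
# into a Poisson deviance with an absolute scale: deviance = 2*(nll - nll_sat).
nll_saturated <- function(observed) {
  pos <- observed > 0
  sum(observed) - sum(observed[pos] * log(observed[pos]))
}

#' Fitting configuration
#'
#' Collects the knobs of [fit_decay()], [choose_endpoint()] and the
#' segmented pipeline.
#'
#' @param mode `"convolution"` (decay convolved with a Gaussian IRF; the
#'   recommended mode) or `"tail"` (post-IRF region fitted directly).
#' @param model_order `"auto"` (fit both and pick by [assess_model_order()]),
#'   `"mono"` or `"bi"`.
#' @param fixed Named list of parameters to freeze at given values (any of
#'   `amp_auto`, `tau_auto`, `amp_signal`, `tau_signal`, `mu`, `sigma`).
#' @param endpoint `"auto"` (selected by [choose_endpoint()]), `"full"`, or a
#'   fixed bin index.
#' @param endpoint_criterion Endpoint selection statistic, maximised over
#'   candidate truncations. `"gof_sqrt"` (default) maximises
#'   `(N - deviance/2) / sqrt(N)` -- the saturated-relative log-likelihood,
#'   mean-adjusted by the expected per-bin deviance, per square root of the
#'   number of data points -- which keeps the full range when the model fits
#'   throughout and cuts where marginal misfit exceeds its expectation.
#'   `"nll_sqrt"` maximises raw NLL over sqrt(N); `"deviance_sqrt"`
#'   minimises deviance over sqrt(N); `"per_bin"` minimises deviance per
#'   bin. See the methods vignette for the analysis behind the default.
#' @param multistart Number of deterministic starts; lifetimes are perturbed
#'   by factors 1, 0.5, 2, 0.25, 4, ... across starts.
#' @param min_counts Minimum total photons for a single-curve fit.
#' @param segment_min_counts Minimum photons for a per-segment fit in the
#'   pipeline; segments below it are QC-rejected, not errors.
#' @param min_window_bins Bins past the peak always kept in the endpoint sweep.
#' @param endpoint_stride Coarse stride (bins) of the endpoint sweep.
#' @param endpoint_refine Fine stride for local refinement around the best
#'   coarse endpoint (within one coarse stride either side).
#' @param tail_start Tail-mode start time (ns); `NULL` derives
#'   peak + 5 * sigma0 from the data.
#' @param min_fraction,min_separation Model-order thresholds: minimum
#'   amplitude fraction of each component and minimum lifetime ratio for the
#'   bi-exponential model to be retained.
#' @param tau_window Plausibility window (ns) for fitted signal lifetimes in
#'   QC filtering.
#' @param periodic Model repetition-rate wrap-around: the fitted curve is the
#'   geometric sum of the decay over all previous excitation pulses,
#'   circularly convolved with the IRF over the laser period (the full
#'   grid). The default `TRUE` matches pulsed TCSPC acquisition, where
#'   long-lived emission from earlier pulses forms a pedestal ahead of the
#'   rising edge; set `FALSE` for gated or time-clipped data.
#' @param seed Integer seed recorded with results (the fit itself is
#'   deterministic).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(mode = c("convolution", "tail"),
                       model_order = c("auto", "mono", "bi"),
                       fixed = list(),
                       endpoint = "auto",
                       endpoint_criterion = c("gof_sqrt", "nll_sqrt",
                                              "deviance_sqrt", "per_bin"),
                       multistart = 3L,
                       min_counts = 100,
                       segment_min_counts = 1000,
                       min_window_bins = 30L,
                       endpoint_stride = 16L,
                       endpoint_refine = 2L,
                       tail_start = NULL,
                       min_fraction = 0.01,
                       min_separation = 1.5,
                       tau_window = c(0.1, 10),
                       periodic = TRUE,
                       seed = 1L) {
  mode <- match.arg(mode)
  model_order <- match.arg(model_order)
  endpoint_criterion <- match.arg(endpoint_criterion)
  if (multistart < 1L) {
    abort_flimr("multistart must be >= 1", "flimr_invalid_parameter")
  }
  structure(
    list(mode = mode, model_order = model_order, fixed = fixed,
         endpoint = endpoint, endpoint_criterion = endpoint_criterion,
         multistart = as.integer(multistart), min_counts = min_counts,
         segment_min_counts = segment_min_counts,
         min_window_bins = as.integer(min_window_bins),
         endpoint_stride = as.integer(endpoint_stride),
         endpoint_refine = as.integer(endpoint_refine),
         tail_start = tail_start, min_fraction = min_fraction,
         min_separation = min_separation, tau_window = tau_window,
         periodic = isTRUE(periodic), seed = as.integer(seed)),
    class = "fit_config"
  )
}

# Parameter names for a given model order and mode.
param_names <- function(order, mode) {
  base <- if (order == "bi") {
    c("amp_auto", "tau_auto", "amp_signal", "tau_signal")
  } else {
    c("amp_signal", "tau_signal")
  }
  if (mode == "convolution") c(base, "mu", "sigma") else base
}

check_fixed <- function(fixed, pnames) {
  bad <- setdiff(names(fixed), pnames)
  if (length(bad) > 0L) {
    abort_flimr(sprintf("fixed parameters not in the model: %s",
                        paste(bad, collapse = ", ")),
                "flimr_invalid_parameter")
  }
}

# Positivity-enforcing transform: log for everything except mu.
theta_from_params <- function(p) {
  out <- p
  lg <- names(p) != "mu"
  out[lg] <- log(pmax(p[lg], 1e-300))
  out
}
params_from_theta <- function(th) {
  out <- th
  lg <- names(th) != "mu"
  out[lg] <- exp(th[lg])
  out
}

# Bin-integrated decay over one laser period with repetition-rate
# wrap-around: the geometric sum over all previous excitation pulses of an
# exponential is the same exponential scaled by 1/(1 - exp(-W/tau)), and the
# first bin additionally collects the sliver wrapped from the end of the
# period.
wrapped_decay_vec <- function(u, dt, window, amplitude, lifetime) {
  out <- numeric(length(u))
  for (c in seq_along(amplitude)) {
    tau <- lifetime[c]
    cc <- amplitude[c] / (1 - exp(-window / tau)) * tau / dt
    v <- cc * (exp(-pmax(u - dt / 2, 0) / tau) - exp(-(u + dt / 2) / tau))
    v[1] <- v[1] + cc * (exp(-(window - dt / 2) / tau) - exp(-window / tau))
    out <- out + v
  }
  out
}

# Build the NLL objective over the full parameter vector. `counts` are the
# first N bins of the data; with `periodic = TRUE` (the default for fitting)
# the model is the wrapped decay circularly convolved with the IRF over the
# FULL grid (the laser period), then truncated to N bins, so endpoint
# truncation never changes the wrap period. Caches the IRF kernel FFT when
# mu and sigma are both frozen (the pipeline's per-segment case).
make_objective <- function(time_ns_full, counts, N, mode, order, fixed,
                           t0 = NULL, periodic = TRUE, eps = 1e-12) {
  if (mode == "convolution") {
    dt <- time_ns_full[2] - time_ns_full[1]
    if (periodic) {
      n <- length(time_ns_full)
      u <- time_ns_full - time_ns_full[1]
      window <- n * dt
      kernel_fft <- function(mu, sigma) {
        k <- stats::dnorm(time_ns_full, mu, sigma)
        s <- sum(k)
        if (!is.finite(s) || s <= 0) return(NULL)
        stats::fft(k / s)
      }
      conv <- function(d, kf) {
        pmax(Re(stats::fft(stats::fft(d) * kf, inverse = TRUE)) / n, 0)[seq_len(N)]
      }
      decay_fn <- function(p) {
        taus <- p[["tau_signal"]]
        amps <- p[["amp_signal"]]
        if (order == "bi") {
          taus <- c(p[["tau_auto"]], taus)
          amps <- c(p[["amp_auto"]], amps)
        }
        wrapped_decay_vec(u, dt, window, amps, taus)
      }
    } else {
      tt <- time_ns_full[seq_len(N)]
      u <- tt - tt[1]
      m <- next_pow2(2L * N)
      pad <- numeric(m - N)
      kernel_fft <- function(mu, sigma) {
        k <- stats::dnorm(tt, mu, sigma)
        s <- sum(k)
        if (!is.finite(s) || s <= 0) return(NULL)
        stats::fft(c(k / s, pad))
      }
      conv <- function(d, kf) {
        pmax(Re(stats::fft(stats::fft(c(d, pad)) * kf,
                           inverse = TRUE)) / m, 0)[seq_len(N)]
      }
      decay_fn <- function(p) {
        taus <- p[["tau_signal"]]
        amps <- p[["amp_signal"]]
        if (order == "bi") {
          taus <- c(p[["tau_auto"]], taus)
          amps <- c(p[["amp_auto"]], amps)
        }
        bin_integrated_decay(u, dt, amps, taus)
      }
    }
    kf_cache <- NULL
    if (all(c("mu", "sigma") %in% names(fixed))) {
      kf_cache <- kernel_fft(fixed$mu, fixed$sigma)
      if (is.null(kf_cache)) {
        abort_flimr("frozen IRF has no mass on the grid",
                    "flimr_invalid_parameter")
      }
    }
    curve_fn <- function(p) {
      kf <- kf_cache %||% kernel_fft(p[["mu"]], p[["sigma"]])
      if (is.null(kf)) return(NULL)
      conv(decay_fn(p), kf)
    }
  } else {
    tt <- time_ns_full[seq_len(N)]
    keep <- tt >= t0
    u <- tt[keep] - t0
    counts <- counts[keep]
    curve_fn <- function(p) {
      d <- p[["amp_signal"]] * exp(-u / p[["tau_signal"]])
      if (order == "bi") {
        d <- d + p[["amp_auto"]] * exp(-u / p[["tau_auto"]])
      }
      d
    }
  }
  list(
    curve = curve_fn,
    counts = counts,
    nll = function(p) {
      cv <- curve_fn(p)
      if (is.null(cv) || any(!is.finite(cv))) return(Inf)
      mm <- pmax(cv, eps)
      sum(mm) - sum(counts * log(mm))
    }
  )
}

# Data-driven initial parameters (see methods vignette): mu0 at the peak bin,
# sigma0 from the rising-edge half width, tau0 from the mean arrival time
# past the peak, amplitudes from total counts (20/80 auto/signal in bi mode).
init_params <- function(time_ns, counts, mode, order, t0 = NULL) {
  dt <- time_ns[2] - time_ns[1]
  peak <- which.max(counts)
  mu0 <- time_ns[peak]
  half <- counts[peak] / 2
  rise <- which(counts[seq_len(peak)] >= half)
  hwhm <- if (length(rise) > 0L) max(mu0 - time_ns[rise[1]], dt / 2) else dt
  sigma0 <- max(hwhm / 1.177, dt / 4)
  after <- seq.int(peak, length(counts))
  wsum <- sum(counts[after])
  tau0 <- if (wsum > 0) {
    max(sum((time_ns[after] - mu0) * counts[after]) / wsum, 2 * dt)
  } else {
    max(diff(range(time_ns)) / 5, 2 * dt)
  }
  total <- sum(counts)
  if (mode == "tail") {
    u <- time_ns - (t0 %||% time_ns[1])
    tau0t <- {
      use <- u >= 0 & counts >= 0
      w <- sum(counts[use])
      if (w > 0) max(sum(u[use] * counts[use]) / w, 2 * dt) else tau0
    }
    if (order == "bi") {
      p <- c(amp_auto = NA, tau_auto = max(0.3 * tau0t, dt),
             amp_signal = NA, tau_signal = 1.2 * tau0t)
      p["amp_auto"] <- 0.2 * total / max(sum(exp(-pmax(u, 0) / p["tau_auto"])), 1)
      p["amp_signal"] <- 0.8 * total / max(sum(exp(-pmax(u, 0) / p["tau_signal"])), 1)
    } else {
      p <- c(amp_signal = total / max(sum(exp(-pmax(u, 0) / tau0t)), 1),
             tau_signal = tau0t)
    }
    return(p)
  }
  u <- time_ns - time_ns[1]
  if (order == "bi") {
    tau_a0 <- max(0.3 * tau0, dt)
    tau_s0 <- 1.2 * tau0
    p <- c(amp_auto = 0.2 * total / max(sum(exp(-u / tau_a0)), 1),
           tau_auto = tau_a0,
           amp_signal = 0.8 * total / max(sum(exp(-u / tau_s0)), 1),
           tau_signal = tau_s0,
           mu = mu0, sigma = sigma0)
  } else {
    p <- c(amp_signal = total / max(sum(exp(-u / tau0)), 1),
           tau_signal = tau0,
           mu = mu0, sigma = sigma0)
  }
  p
}

# Minimize the objective over the free parameters with deterministic
# multistart; ties in NLL broken toward smaller tau_signal.
optimize_params <- function(obj, p0, free, multistart) {
  if (length(free) == 0L) {
    return(list(params = p0, nll = obj$nll(p0), converged = TRUE))
  }
  scales <- c(1, 0.5, 2, 0.25, 4, 0.1, 8)
  scales <- scales[seq_len(min(multistart, length(scales)))]
  tau_free <- intersect(free, c("tau_auto", "tau_signal"))
  best <- NULL
  for (f in scales) {
    ps <- p0
    ps[tau_free] <- ps[tau_free] * f
    th0 <- theta_from_params(ps)[free]
    wrapped <- function(th) {
      pp <- p0
      pp[free] <- params_from_theta(stats::setNames(th, free))
      v <- obj$nll(pp)
      if (!is.finite(v)) 1e12 else v
    }
    if (length(free) == 1L) {
      op <- stats::optimize(wrapped, interval = c(th0 - 6, th0 + 6),
                            tol = 1e-10)
      sol <- list(par = op$minimum, value = op$objective, convergence = 0L)
    } else {
      sol <- stats::optim(th0, wrapped, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      # one polishing restart from the solution (fresh simplex)
      sol2 <- stats::optim(sol$par, wrapped, method = "Nelder-Mead",
                           control = list(maxit = 1000, reltol = 1e-10))
      if (sol2$value <= sol$value) sol <- sol2
    }
    pfit <- p0
    pfit[free] <- params_from_theta(stats::setNames(sol$par, free))
    cand <- list(params = pfit, nll = sol$value,
                 converged = sol$convergence == 0L)
    if (is.null(best) ||
        cand$nll < best$nll - 1e-9 ||
        (abs(cand$nll - best$nll) <= 1e-9 &&
         cand$params[["tau_signal"]] < best$params[["tau_signal"]])) {
      best <- cand
    }
  }
  best
}

# Fit at a fixed endpoint (first N bins). Returns params/nll/converged.
fit_at_endpoint <- function(time_ns, counts, N, mode, order, fixed,
                            multistart, t0 = NULL, init = NULL,
                            periodic = TRUE) {
  tt <- time_ns[seq_len(N)]
  nn <- counts[seq_len(N)]
  obj <- make_objective(time_ns, nn, N, mode, order, fixed, t0 = t0,
                        periodic = periodic)
  if (mode == "tail") {
    keep <- tt >= t0
    tt <- tt[keep]
    nn <- nn[keep]
  }
  pnames <- param_names(order, mode)
  p0 <- init_params(tt, nn, mode, order, t0 = t0)[pnames]
  names(p0) <- pnames
  if (!is.null(init)) {
    common <- intersect(names(init), pnames)
    p0[common] <- init[common]
  }
  for (nm in names(fixed)) p0[[nm]] <- fixed[[nm]]
  free <- setdiff(pnames, names(fixed))
  res <- optimize_params(obj, p0, free, multistart)
  # restore exact frozen values (they are never touched by the optimizer,
  # but make the contract explicit)
  for (nm in names(fixed)) res$params[[nm]] <- fixed[[nm]]
  # keep the shorter-lifetime component labelled autofluorescence when both
  # lifetimes were free
  if (order == "bi" && all(c("tau_auto", "tau_signal") %in% free) &&
      res$params[["tau_auto"]] > res$params[["tau_signal"]]) {
    res$params[c("tau_auto", "tau_signal")] <- res$params[c("tau_signal", "tau_auto")]
    res$params[c("amp_auto", "amp_signal")] <- res$params[c("amp_signal", "amp_auto")]
  }
  res$n_used <- length(obj$counts)
  res$nll_sat <- nll_saturated(obj$counts)
  res
}

endpoint_score <- function(nll, nll_sat, n_used, criterion) {
  dev <- 2 * (nll - nll_sat)
  switch(criterion,
    gof_sqrt = (n_used - dev / 2) / sqrt(n_used),
    nll_sqrt = nll / sqrt(n_used),
    deviance_sqrt = -dev / sqrt(n_used),
    per_bin = -dev / n_used
  )
}

#' Automatic endpoint selection
#'
#' Treats the cutoff bin of the fitted data range as a fit variable so that
#' background or scattered light late in the TCSPC window does not drive the
#' lifetime away from its true value. The decay is refit at a coarse grid of
#' candidate endpoints (every `endpoint_stride` bins from
#' peak + `min_window_bins` to the last bin), the selection statistic is
#' evaluated at each, and the best candidate is refined locally at stride
#' `endpoint_refine`. The sweep trace is retained for plotting.
#'
#' @param hist Data frame with `time_ns` and `counts`.
#' @param config A [fit_config()]; `config$endpoint_criterion` chooses the
#'   statistic.
#' @param order Model order to sweep with (`"mono"` or `"bi"`); defaults to
#'   the config's order, with `"auto"` swept as `"bi"`.
#' @return A list with `endpoint` (bin index), `fit` (raw fit at the chosen
#'   endpoint), and `sweep` (tibble of endpoint, n_bins, nll, deviance and
#'   the selection score, higher = preferred).
#' @export
choose_endpoint <- function(hist, config = fit_config(), order = NULL) {
  cols <- decay_cols(hist, value_cols = "counts")
  time_ns <- cols$time_ns
  counts <- cols$value
  validate_time_grid(time_ns, min_bins = 8L)
  order <- order %||% if (config$model_order == "mono") "mono" else "bi"
  fixed <- config$fixed
  check_fixed(fixed, param_names(order, config$mode))
  t0 <- resolve_tail_start(time_ns, counts, config)
  n <- length(time_ns)
  peak <- which.max(counts)
  start <- min(peak + config$min_window_bins, n)
  cand <- unique(c(seq.int(start, n, by = config$endpoint_stride), n))
  if (length(cand) < 2L) {
    abort_flimr("fewer than 2 candidate endpoints; grid too short for a sweep",
                "flimr_degenerate_range")
  }
  # The sweep always fits the single-pulse (aperiodic) model: the periodic
  # wrap term can mimic a uniform background floor at short windows, which
  # lets contaminated short-window fits score as well as clean ones and
  # collapses the selection to the minimum window. The single-pulse model is
  # rigid against that absorption, so misfit from background shows up in the
  # score. The returned fit is then re-estimated at the selected endpoint
  # under the configured model (see below).
  sweep_one <- function(N, init) {
    # warm-started refits need no multistart; cold starts get the full budget
    ms <- if (is.null(init)) config$multistart else 1L
    fit_at_endpoint(time_ns, counts, N, config$mode, order, fixed,
                    ms, t0 = t0, init = init, periodic = FALSE)
  }
  dt_grid <- time_ns[2] - time_ns[1]
  # lifetimes below the bin width are unresolvable spikes; a warm-start chain
  # that drifts there is restarted from data-driven initial values
  degenerate <- function(f) {
    any(f$params[intersect(names(f$params),
                           c("tau_auto", "tau_signal"))] < dt_grid)
  }
  fits <- vector("list", length(cand))
  init <- NULL
  for (i in seq_along(cand)) {
    fits[[i]] <- sweep_one(cand[i], init)
    if (degenerate(fits[[i]])) {
      refit <- sweep_one(cand[i], NULL)
      if (refit$nll <= fits[[i]]$nll + 1e-6) fits[[i]] <- refit
    }
    init <- fits[[i]]$params  # warm start the next truncation
  }
  scores <- vapply(fits, function(f) {
    endpoint_score(f$nll, f$nll_sat, f$n_used, config$endpoint_criterion)
  }, numeric(1))
  best_i <- which.max(scores)
  # local refinement around the best coarse endpoint
  lo <- max(start, cand[best_i] - config$endpoint_stride)
  hi <- min(n, cand[best_i] + config$endpoint_stride)
  fine <- setdiff(unique(c(seq.int(lo, hi, by = config$endpoint_refine), hi)), cand)
  fine_fits <- vector("list", length(fine))
  init <- fits[[best_i]]$params
  for (i in seq_along(fine)) {
    fine_fits[[i]] <- sweep_one(fine[i], init)
  }
  all_ep <- c(cand, fine)
  all_fits <- c(fits, fine_fits)
  all_scores <- vapply(all_fits, function(f) {
    endpoint_score(f$nll, f$nll_sat, f$n_used, config$endpoint_criterion)
  }, numeric(1))
  ord_i <- order(all_ep)
  all_ep <- all_ep[ord_i]
  all_fits <- all_fits[ord_i]
  all_scores <- all_scores[ord_i]
  best <- which.max(all_scores)
  sweep <- tibble::tibble(
    endpoint = all_ep,
    n_bins = vapply(all_fits, function(f) f$n_used, numeric(1)),
    nll = vapply(all_fits, function(f) f$nll, numeric(1)),
    deviance = vapply(all_fits, function(f) 2 * (f$nll - f$nll_sat), numeric(1)),
    score = all_scores,
    selected = seq_along(all_ep) == best
  )
  final <- all_fits[[best]]
  if (config$periodic) {
    # refit under the periodic model, both warm-started from the sweep winner
    # and cold-started from data-driven inits (the warm start can sit in a
    # spike basin); keep the better likelihood
    warm <- fit_at_endpoint(time_ns, counts, all_ep[best], config$mode,
                            order, fixed, config$multistart, t0 = t0,
                            init = final$params, periodic = TRUE)
    cold <- fit_at_endpoint(time_ns, counts, all_ep[best], config$mode,
                            order, fixed, config$multistart, t0 = t0,
                            periodic = TRUE)
    final <- if (warm$nll <= cold$nll) warm else cold
  }
  list(endpoint = all_ep[best], fit = final, sweep = sweep, t0 = t0)
}

resolve_tail_start <- function(time_ns, counts, config) {
  if (config$mode != "tail") return(NULL)
  if (!is.null(config$tail_start)) return(config$tail_start)
  dt <- time_ns[2] - time_ns[1]
  peak <- which.max(counts)
  p0 <- init_params(time_ns, counts, "convolution", "mono")
  time_ns[peak] + ceiling(5 * p0[["sigma"]] / dt) * dt
}

#' Fit a decay histogram by Poisson maximum likelihood
#'
#' Minimises the Poisson negative log-likelihood of the model curve over the
#' non-frozen parameters, with positivity of lifetimes, amplitudes and the
#' IRF width enforced by a log transform, deterministic multistart over
#' lifetime perturbations, and (optionally) automatic endpoint and
#' model-order selection. In convolution mode the free parameters of a
#' bi-exponential full-field fit are the two amplitudes, two lifetimes and
#' the Gaussian IRF centre and width; any subset can be frozen through
#' `config$fixed` (the pipeline freezes `tau_auto`, `mu`, `sigma` for
#' per-segment fits).
#'
#' @param hist Data frame with columns `time_ns` (uniformly spaced bin
#'   centres) and `counts` (non-negative integers).
#' @param config A [fit_config()].
#' @param init Optional named vector (or `flim_fit`) of starting parameters.
#' @return An object of class `flim_fit`; see [tidy.flim_fit()] and
#'   [glance.flim_fit()].
#' @examples
#' truth <- simulation_truth(tau_signal = 2.5, fraction_auto = 0,
#'                           n_photons = 20000)
#' hist <- bin_photons(sample_photons(truth, seed = 1), truth)
#' fit <- fit_decay(hist, fit_config(model_order = "mono", endpoint = "full"))
#' fit$signal_lifetime
#' @export
fit_decay <- function(hist, config = fit_config(), init = NULL) {
  cols <- decay_cols(hist, value_cols = "counts")
  time_ns <- cols$time_ns
  counts <- cols$value
  validate_time_grid(time_ns, min_bins = 8L)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_flimr("counts must be non-negative integers", "flimr_format_error")
  }
  if (sum(counts) < config$min_counts) {
    abort_flimr(sprintf("total counts %d below minimum %d",
                        sum(counts), config$min_counts),
                "flimr_low_counts")
  }
  if (inherits(init, "flim_fit")) init <- init$params
  n <- length(time_ns)
  order <- config$model_order
  primary <- if (order == "mono") "mono" else "bi"
  check_fixed(config$fixed, param_names(primary, config$mode))
  t0 <- resolve_tail_start(time_ns, counts, config)

  sweep <- NULL
  if (identical(config$endpoint, "auto")) {
    ep <- choose_endpoint(hist, config, order = primary)
    N <- ep$endpoint
    fit_primary <- ep$fit
    sweep <- ep$sweep
    t0 <- ep$t0
  } else {
    N <- if (identical(config$endpoint, "full")) n else as.integer(config$endpoint)
    if (N < 8L || N > n) {
      abort_flimr("fixed endpoint outside the grid", "flimr_invalid_parameter")
    }
    fit_primary <- fit_at_endpoint(time_ns, counts, N, config$mode, primary,
                                   config$fixed, config$multistart,
                                   t0 = t0, init = init,
                                   periodic = config$periodic)
  }

  chosen_order <- primary
  fit_final <- fit_primary
  if (order == "auto") {
    fixed_mono <- config$fixed[intersect(names(config$fixed),
                                         param_names("mono", config$mode))]
    fit_mono <- fit_at_endpoint(time_ns, counts, N, config$mode, "mono",
                                fixed_mono, config$multistart, t0 = t0,
                                periodic = config$periodic)
    r_bi <- new_flim_fit(fit_primary, "bi", config, hist, N, sweep, t0)
    r_mono <- new_flim_fit(fit_mono, "mono", config, hist, N, sweep, t0)
    chosen_order <- assess_model_order(r_bi, r_mono,
                                       min_fraction = config$min_fraction,
                                       min_separation = config$min_separation)
    return(if (chosen_order == "bi") r_bi else r_mono)
  }
  new_flim_fit(fit_final, chosen_order, config, hist, N, sweep, t0)
}

# Assemble the user-facing fit object.
new_flim_fit <- function(raw, order, config, hist, N, sweep, t0,
                         status = "ok") {
  p <- raw$params
  time_ns <- hist$time_ns[seq_len(N)]
  dt <- time_ns[2] - time_ns[1]
  if (order == "bi") {
    # component share of fitted counts over the used window: the integral
    # A * tau * (1 - exp(-T/tau)) is robust for spike-like lifetimes where
    # pointwise sums over bin centres mis-state the contribution
    T_used <- N * dt
    s_auto <- p[["amp_auto"]] * p[["tau_auto"]] *
      (1 - exp(-T_used / p[["tau_auto"]]))
    s_sig <- p[["amp_signal"]] * p[["tau_signal"]] *
      (1 - exp(-T_used / p[["tau_signal"]]))
    fr <- c(auto = s_auto, signal = s_sig) / max(s_auto + s_sig, 1e-300)
  } else {
    fr <- c(auto = 0, signal = 1)
  }
  structure(
    list(
      params = p,
      mode = config$mode,
      model_order = order,
      nll = raw$nll,
      n_bins_used = N,
      n_points_used = raw$n_used,
      converged = raw$converged,
      signal_lifetime = unname(p[["tau_signal"]]),
      auto_lifetime = if (order == "bi") unname(p[["tau_auto"]]) else NA_real_,
      mu = if (config$mode == "convolution") unname(p[["mu"]]) else NA_real_,
      sigma = if (config$mode == "convolution") unname(p[["sigma"]]) else NA_real_,
      amplitude_fractions = fr,
      npar = length(setdiff(param_names(order, config$mode), names(config$fixed))),
      fixed = config$fixed,
      t0 = t0,
      periodic = config$periodic %||% TRUE,
      endpoint_sweep = sweep,
      data = tibble::as_tibble(hist[c("time_ns", "counts")]),
      status = status,
      seed = config$seed
    ),
    class = "flim_fit"
  )
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf("<flim_fit: %s-exponential %s fit%s>\n",
              x$model_order, x$mode,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  signal lifetime: %.4f ns\n", x$signal_lifetime))
  if (!is.na(x$auto_lifetime)) {
    cat(sprintf("  autofluorescence lifetime: %.4f ns (fraction %.3f)\n",
                x$auto_lifetime, x$amplitude_fractions[["auto"]]))
  }
  if (!is.na(x$mu)) {
    cat(sprintf("  IRF: mu = %.4f ns, sigma = %.4f ns\n", x$mu, x$sigma))
  }
  cat(sprintf("  NLL: %.4f over %d of %d bins\n",
              x$nll, x$n_bins_used, nrow(x$data)))
  invisible(x)
}

#' Extract the fitted decay model from a fit
#'
#' @param x A `flim_fit`.
#' @return A [decay_model()] reproducing the fitted curve via [model_curve()].
#' @export
as_decay_model <- function(x) {
  p <- x$params
  amps <- if (x$model_order == "bi") c(p[["amp_auto"]], p[["amp_signal"]]) else p[["amp_signal"]]
  taus <- if (x$model_order == "bi") c(p[["tau_auto"]], p[["tau_signal"]]) else p[["tau_signal"]]
  irf <- if (x$mode == "convolution") gaussian_irf(p[["mu"]], p[["sigma"]]) else NULL
  decay_model(amps, taus, irf = irf, t0 = if (x$mode == "tail") x$t0 else NULL)
}

#' Fitted expected counts for a flim_fit
#'
#' @param object A `flim_fit`.
#' @param ... Unused.
#' @return Tibble `time_ns`, `expected` over the bins used in the fit.
#' @export
fitted.flim_fit <- function(object, ...) {
  if (object$mode == "convolution" && isTRUE(object$periodic)) {
    # wrap period is the full grid; truncate after evaluation
    full <- model_curve(object$data$time_ns, as_decay_model(object),
                        periodic = TRUE)
    return(full[seq_len(object$n_bins_used), ])
  }
  model_curve(object$data$time_ns[seq_len(object$n_bins_used)],
              as_decay_model(object))
}

#' Choose between mono- and bi-exponential fits
#'
#' The bi-exponential model is retained only if it looks genuinely
#' two-component: each amplitude fraction at least `min_fraction`, lifetime
#' ratio at least `min_separation`, and a BIC on the Poisson likelihood
#' (penalising the two extra parameters) favouring it. Otherwise the fit
#' falls back to mono-exponential.
#'
#' @param bi,mono `flim_fit` objects fitted on the same histogram and
#'   endpoint.
#' @param min_fraction Minimum amplitude fraction per component.
#' @param min_separation Minimum `tau_signal / tau_auto` ratio.
#' @return `"mono"` or `"bi"`.
#' @export
assess_model_order <- function(bi, mono, min_fraction = 0.01,
                               min_separation = 1.5) {
  if (!bi$converged && !mono$converged) {
    abort_flimr("neither model order converged", "flimr_fit_failure")
  }
  if (!bi$converged) return("mono")
  if (!mono$converged) return("bi")
  if (bi$n_bins_used != mono$n_bins_used) {
    abort_flimr("model-order comparison requires fits at the same endpoint",
                "flimr_invalid_parameter")
  }
  fr <- bi$amplitude_fractions
  if (any(fr < min_fraction)) return("mono")
  if (bi$signal_lifetime / bi$auto_lifetime < min_separation) return("mono")
  N <- bi$n_points_used
  bic_bi <- 2 * bi$nll + bi$npar * log(N)
  bic_mono <- 2 * mono$nll + mono$npar * log(N)
  if (bic_bi < bic_mono) "bi" else "mono"
}
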