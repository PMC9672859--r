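# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' One row per fitted parameter with its value and whether it was frozen.
#'
#' @param x A `flim_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `fixed`.
#' @export
tidy.flim_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          fixed = logical()))
  }
  tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params),
    fixed = names(x$params) %in% names(x$fixed)
  )
}

#' One-row summary of a decay fit
#'
#' @param x A `flim_fit`.
#' @param ... Unused.
#' @return Tibble with the lifetimes, IRF parameters, amplitude fractions,
#'   NLL, endpoint and convergence status.
#' @export
glance.flim_fit <- function(x, ...) {
  tibble::tibble(
    model_order = x$model_order,
    mode = x$mode,
    tau_signal_ns = x$signal_lifetime,
    tau_auto_ns = x$auto_lifetime,
    irf_mu_ns = x$mu,
    irf_sigma_ns = x$sigma,
    frac_auto = unname(x$amplitude_fractions[["auto"]]),
    frac_signal = unname(x$amplitude_fractions[["signal"]]),
    nll = x$nll,
    n_bins_used = x$n_bins_used,
    converged = x$converged,
    status = x$status
  )
}

#' Tidy pipeline results
#'
#' @param x A `flim_pipeline`.
#' @param ... Unused.
#' @return The per-segment results tibble.
#' @export
tidy.flim_pipeline <- function(x, ...) x$results

#' One-row summary of a pipeline run
#'
#' @param x A `flim_pipeline`.
#' @param ... Unused.
#' @return Tibble with segment counts, calibration parameters and seed.
#' @export
glance.flim_pipeline <- function(x, ...) {
  tibble::tibble(
    acquisition_id = x$acquisition_id,
    n_segments = nrow(x$results),
    n_accepted = sum(x$results$qc_accepted),
    calibration_order = x$calibration$model_order_used,
    tau_auto_ns = x$calibration$tau_auto,
    irf_mu_ns = x$calibration$mu,
    irf_sigma_ns = x$calibration$sigma,
    n_timepoints = x$n_timepoints,
    seed = x$seed
  )
}
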