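# ggplot2 visualisations of fits and pipeline output.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decay fit
#'
#' Observed counts (log scale) with the fitted curve and, for bi-exponential
#' fits, the autofluorescence (donor-unrelated) component shown dotted; the
#' selected endpoint is marked when an endpoint sweep was run.
#'
#' @param object A `flim_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flim_fit <- function(object, ...) {
  dat <- object$data
  fit <- fitted(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_ns, y = .data$counts)) +
    ggplot2::geom_point(size = 0.6, colour = "grey30") +
    ggplot2::geom_line(data = fit,
                       ggplot2::aes(y = .data$expected),
                       colour = "red", linewidth = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "photon counts",
                  title = sprintf("%s-exponential fit: tau_signal = %.3f ns",
                                  object$model_order, object$signal_lifetime)) +
    ggplot2::theme_minimal()
  if (object$model_order == "bi" && object$mode == "convolution") {
    tt <- dat$time_ns[seq_len(object$n_bins_used)]
    auto_m <- decay_model(object$params[["amp_auto"]],
                          object$params[["tau_auto"]],
                          irf = gaussian_irf(object$mu, object$sigma))
    p <- p + ggplot2::geom_line(
      data = model_curve(tt, auto_m),
      ggplot2::aes(y = .data$expected),
      colour = "orange", linetype = "dotted", linewidth = 0.7
    )
  }
  if (!is.null(object$endpoint_sweep)) {
    sel_t <- dat$time_ns[object$n_bins_used]
    p <- p + ggplot2::geom_vline(xintercept = sel_t, linetype = "dashed",
                                 colour = "steelblue")
  }
  p
}

#' Plot the endpoint-selection sweep
#'
#' The goodness-of-fit score of the sequential truncated fits used to
#' threshold background light, with the selected endpoint marked.
#'
#' @param fit A `flim_fit` fitted with `endpoint = "auto"` (or the `sweep`
#'   tibble from [choose_endpoint()]).
#' @return A ggplot.
#' @export
plot_endpoint_sweep <- function(fit) {
  sweep <- if (inherits(fit, "flim_fit")) fit$endpoint_sweep else fit
  if (is.null(sweep)) {
    abort_flimr("no endpoint sweep stored; fit with endpoint = \"auto\"",
                "flimr_invalid_parameter")
  }
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$endpoint, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = sweep[sweep$selected, ],
                        colour = "red", size = 2) +
    ggplot2::labs(x = "endpoint (bin)", y = "selection score",
                  title = "Endpoint sweep (selected endpoint in red)") +
    ggplot2::theme_minimal()
}

#' Plot per-segment lifetimes from a pipeline run
#'
#' @param object A `flim_pipeline`.
#' @param ... Unused.
#' @return A ggplot of signal lifetime per segment, QC rejections hollow.
#' @export
autoplot.flim_pipeline <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = factor(.data$segment_label),
                                    y = .data$tau_signal_ns,
                                    shape = .data$qc_accepted)) +
    ggplot2::geom_point(size = 2.5, colour = "steelblue") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "QC accepted") +
    ggplot2::labs(x = "segment", y = "signal lifetime (ns)",
                  title = sprintf("Per-segment signal lifetimes (%s)",
                                  object$acquisition_id)) +
    ggplot2::theme_minimal()
}
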