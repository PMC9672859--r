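# Two-stage segmented FLIM analysis: aggregate photons per segment across
# timepoints, calibrate autofluorescence + IRF on the full field, fit each
# segment for its signal lifetime with the calibration frozen, QC-filter,
# and export.

#' Aggregate timepoints into per-segment and full-field histograms
#'
#' Bin-wise integer sum of micro-time counts over each segment's pixels over
#' all timepoints, plus the full-field histogram over every pixel (including
#' non-segmented tissue, which maximises the photons available for the
#' autofluorescence calibration).
#'
#' @param images List of [flim_image()] timepoints (or a single image).
#' @param segments Segment tibble from [mask_segments()].
#' @return List with `segments` (the tibble with `histogram` and
#'   `photon_count` attached) and `full_field` (histogram tibble).
#' @export
aggregate_timepoints <- function(images, segments) {
  if (inherits(images, "flim_image")) images <- list(images)
  total <- sum_flim_images(images)
  list(
    segments = attach_histograms(segments, total),
    full_field = full_field_histogram(total)
  )
}

#' Calibrate autofluorescence and instrument response on the full field
#'
#' Fits the full field of view in convolution mode with automatic
#' model-order selection: a Gaussian IRF convolved with a bi-exponential
#' establishes the autofluorescence lifetime (the shorter component) and the
#' IRF parameters; if the bi-exponential is not warranted the field falls
#' back to mono-exponential and segments are later fitted mono with only the
#' IRF frozen.
#'
#' @param full_hist Full-field decay histogram (`time_ns`, `counts`).
#' @param config A [fit_config()]; its mode is forced to `"convolution"`.
#' @return A list of class `field_calibration`: `tau_auto` (NA when mono),
#'   `mu`, `sigma`, `model_order_used`, `nll`, `fit`.
#' @export
calibrate_field <- function(full_hist, config = fit_config()) {
  cols <- decay_cols(full_hist, value_cols = "counts")
  if (sum(cols$value) < 10 * config$segment_min_counts) {
    abort_flimr(sprintf(
      "full-field histogram has %d counts; calibration needs at least 10x the segment minimum (%d)",
      sum(cols$value), 10 * config$segment_min_counts), "flimr_low_counts")
  }
  cfg <- config
  cfg$mode <- "convolution"
  cfg$model_order <- "auto"
  fit <- tryCatch(
    fit_decay(full_hist, cfg),
    flimr_fit_failure = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    abort_flimr("full-field calibration fit did not converge; segments cannot be decoupled",
                "flimr_calibration_failure")
  }
  structure(
    list(
      tau_auto = if (fit$model_order == "bi") fit$auto_lifetime else NA_real_,
      mu = fit$mu, sigma = fit$sigma,
      model_order_used = fit$model_order,
      nll = fit$nll,
      n_bins_used = fit$n_bins_used,
      fit = fit
    ),
    class = "field_calibration"
  )
}

#' @export
print.field_calibration <- function(x, ...) {
  cat(sprintf("<field_calibration: %s-exponential full-field fit>\n",
              x$model_order_used))
  if (!is.na(x$tau_auto)) {
    cat(sprintf("  autofluorescence lifetime: %.4f ns\n", x$tau_auto))
  }
  cat(sprintf("  IRF: mu = %.4f ns, sigma = %.4f ns\n", x$mu, x$sigma))
  invisible(x)
}

#' Fit one segment with the field calibration frozen
#'
#' Stage two of the decoupling: `tau_auto`, `mu` and `sigma` are frozen at
#' the calibration values, leaving only the signal lifetime and the two
#' amplitudes free (amplitude and lifetime in mono fall-back), so signal
#' fits remain possible even when the per-segment photon count could not
#' support a joint six-parameter fit. The endpoint is chosen per segment.
#'
#' @param seg_hist Segment decay histogram.
#' @param calibration A [calibrate_field()] result.
#' @param config A [fit_config()].
#' @return A `flim_fit`, or an object with `status = "low_counts"` (and
#'   `converged = FALSE`) when the segment has fewer than
#'   `config$segment_min_counts` photons; low counts are a QC outcome, not
#'   an error.
#' @export
fit_segment <- function(seg_hist, calibration, config = fit_config()) {
  cols <- decay_cols(seg_hist, value_cols = "counts")
  total <- sum(cols$value)
  if (total < config$segment_min_counts) {
    return(structure(
      list(params = NULL, mode = "convolution",
           model_order = calibration$model_order_used,
           nll = NA_real_, n_bins_used = NA_integer_,
           n_points_used = NA_integer_, converged = FALSE,
           signal_lifetime = NA_real_, auto_lifetime = NA_real_,
           mu = calibration$mu, sigma = calibration$sigma,
           amplitude_fractions = c(auto = NA_real_, signal = NA_real_),
           npar = 0L, fixed = list(), t0 = NULL, endpoint_sweep = NULL,
           data = tibble::as_tibble(seg_hist), status = "low_counts",
           seed = config$seed),
      class = "flim_fit"
    ))
  }
  cfg <- config
  cfg$mode <- "convolution"
  if (calibration$model_order_used == "bi") {
    cfg$model_order <- "bi"
    cfg$fixed <- list(tau_auto = calibration$tau_auto,
                      mu = calibration$mu, sigma = calibration$sigma)
  } else {
    cfg$model_order <- "mono"
    cfg$fixed <- list(mu = calibration$mu, sigma = calibration$sigma)
  }
  cfg$min_counts <- min(config$min_counts, config$segment_min_counts)
  fit_decay(seg_hist, cfg)
}

#' Quality-control filter for segment results
#'
#' Applies the automatic rejection predicates: photon count below the
#' minimum, unconverged fit, fitted signal lifetime outside the plausibility
#' window, or an endpoint window shorter than the minimum. Every rejection
#' carries a reason.
#'
#' @param results Tibble with columns `photon_count`, `converged`,
#'   `tau_signal_ns`, `n_bins_used` (as produced by [run_flim_pipeline()]).
#' @param min_counts Minimum photons per segment.
#' @param tau_window Plausible signal-lifetime window in ns.
#' @param min_bins Minimum endpoint window in bins.
#' @return The tibble with `qc_accepted` (logical) and `qc_reason`
#'   (`""` when accepted) columns replaced.
#' @export
qc_filter <- function(results, min_counts = 1000, tau_window = c(0.1, 10),
                      min_bins = 30L) {
  reason <- rep("", nrow(results))
  nb <- results$n_bins_used
  reason[is.na(nb) | nb < min_bins] <- "short_window"
  ts <- results$tau_signal_ns
  reason[!is.na(ts) & (ts < tau_window[1] | ts > tau_window[2])] <- "tau_out_of_range"
  reason[!results$converged] <- "unconverged"
  reason[results$photon_count < min_counts] <- "low_counts"
  results$qc_accepted <- reason == ""
  results$qc_reason <- reason
  results
}

#' Normalise lifetimes to the per-experiment mean
#'
#' Each value is divided by the grand mean of all values in its experiment
#' group, so each experiment's normalised values average exactly 1; this
#' removes between-session offsets before pooling.
#'
#' @param df Data frame of per-segment values.
#' @param value Column name (string) of the values to normalise.
#' @param group Column name (string) of the experiment labels.
#' @param out Name of the output column.
#' @return The data frame with the normalised column added.
#' @export
normalize_group <- function(df, value = "tau_signal_ns", group = "experiment",
                            out = paste0(value, "_norm")) {
  if (nrow(df) == 0L) {
    df[[out]] <- numeric(0)
    return(df)
  }
  g <- df[[group]]
  v <- df[[value]]
  means <- tapply(v, g, mean)
  df[[out]] <- v / as.numeric(means[as.character(g)])
  df
}

#' Run the full segmented FLIM pipeline
#'
#' Executes, in order: segment extraction from the label mask, ellipse shape
#' metrics, photon aggregation across timepoints, full-field calibration,
#' per-segment signal-lifetime fits with the calibration frozen, and QC
#' filtering. At most `target_segments` segments are analysed, keeping the
#' brightest (descending photon count). Deterministic given
#' `(inputs, config, seed)`.
#'
#' @param images List of [flim_image()] timepoints.
#' @param mask Integer label mask matrix (or path to a TIFF).
#' @param config A [fit_config()].
#' @param target_segments Soft cap on segments per image (default 15).
#' @param acquisition_id Identifier recorded in the results table.
#' @return Object of class `flim_pipeline` with `results` (tibble, one row
#'   per analysed segment), `calibration`, `segments` (with histograms and
#'   shape metrics), `full_field` histogram, and bookkeeping fields. Use
#'   [tidy.flim_pipeline()] for the results table.
#' @export
run_flim_pipeline <- function(images, mask, config = fit_config(),
                              target_segments = 15L,
                              acquisition_id = "acq") {
  if (is.character(mask)) mask <- read_mask_tiff(mask)
  segments <- mask_segments(mask)
  if (nrow(segments) == 0L) {
    abort_flimr("no segments in mask", "flimr_no_segments")
  }
  segments <- ellipse_shape(segments)
  agg <- aggregate_timepoints(images, segments)
  segments <- agg$segments
  segments <- dplyr::arrange(segments, dplyr::desc(.data$photon_count))
  analysed <- utils::head(segments, target_segments)
  calibration <- calibrate_field(agg$full_field, config)
  fits <- purrr::map(analysed$histogram, function(h) {
    fit_segment(h, calibration, config)
  })
  results <- tibble::tibble(
    acquisition_id = acquisition_id,
    segment_label = analysed$label,
    tau_signal_ns = purrr::map_dbl(fits, "signal_lifetime"),
    tau_auto_ns = calibration$tau_auto,
    irf_mu_ns = calibration$mu,
    irf_sigma_ns = calibration$sigma,
    nll = purrr::map_dbl(fits, "nll"),
    n_bins_used = purrr::map_int(fits, ~ as.integer(.x$n_bins_used)),
    photon_count = analysed$photon_count,
    aspect_ratio = analysed$aspect_ratio,
    roundness = analysed$roundness,
    converged = purrr::map_lgl(fits, "converged")
  )
  results <- qc_filter(results,
                       min_counts = config$segment_min_counts,
                       tau_window = config$tau_window,
                       min_bins = config$min_window_bins)
  structure(
    list(results = results, calibration = calibration,
         segments = analysed, fits = fits, full_field = agg$full_field,
         config = config, seed = config$seed,
         acquisition_id = acquisition_id,
         n_timepoints = if (inherits(images, "flim_image")) 1L else length(images)),
    class = "flim_pipeline"
  )
}

#' @export
print.flim_pipeline <- function(x, ...) {
  cat(sprintf("<flim_pipeline: %s, %d segments analysed (%d accepted), %s calibration>\n",
              x$acquisition_id, nrow(x$results), sum(x$results$qc_accepted),
              x$calibration$model_order_used))
  print(x$results)
  invisible(x)
}

#' Write the pipeline results table as CSV
#'
#' Columns: acquisition_id, segment_label, tau_signal_ns, tau_auto_ns,
#' irf_mu_ns, irf_sigma_ns, nll, n_bins_used, photon_count, aspect_ratio,
#' roundness, qc_accepted, qc_reason.
#'
#' @param pipeline A `flim_pipeline` (or its results tibble).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(pipeline, path) {
  res <- if (inherits(pipeline, "flim_pipeline")) pipeline$results else pipeline
  cols <- c("acquisition_id", "segment_label", "tau_signal_ns", "tau_auto_ns",
            "irf_mu_ns", "irf_sigma_ns", "nll", "n_bins_used", "photon_count",
            "aspect_ratio", "roundness", "qc_accepted", "qc_reason")
  readr::write_csv(res[, intersect(cols, names(res))], path)
  invisible(path)
}
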