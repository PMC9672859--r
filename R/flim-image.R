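# Per-pixel micro-time photon data reconstructed from an event stream or
# simulated directly.

#' FLIM image container
#'
#' Wraps a per-pixel micro-time count cube: an integer array
#' `[rows, cols, n_bins]` plus the micro-time bin width `dt` (ns).
#'
#' @param counts 3D array of photon counts, dimensions rows x cols x bins.
#' @param dt Micro-time bin width in ns.
#' @return An object of class `flim_image`.
#' @export
flim_image <- function(counts, dt) {
  if (length(dim(counts)) != 3L) {
    abort_flimr("counts must be a rows x cols x bins array", "flimr_format_error")
  }
  if (!is.finite(dt) || dt <= 0) {
    abort_flimr("dt must be positive", "flimr_invalid_parameter")
  }
  structure(list(counts = counts, dt = dt), class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_image: %d x %d px, %d micro-time bins (dt = %.5g ns), %s photons>\n",
              d[1], d[2], d[3], x$dt, format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.flim_image <- function(x) dim(x$counts)

flim_time_axis <- function(image) {
  nb <- dim(image$counts)[3]
  (seq_len(nb) - 0.5) * image$dt
}

#' Sum two or more FLIM images (e.g. timepoints)
#'
#' @param images List of `flim_image` objects with identical dimensions and
#'   `dt`.
#' @return A single `flim_image` with bin-wise integer-summed counts.
#' @export
sum_flim_images <- function(images) {
  if (length(images) == 0L) {
    abort_flimr("no images to sum", "flimr_incompatible_acquisition")
  }
  d <- dim(images[[1]]$counts)
  dt <- images[[1]]$dt
  for (im in images[-1]) {
    if (!identical(dim(im$counts), d) || abs(im$dt - dt) > 1e-12 * dt) {
      abort_flimr("timepoint images differ in dimensions or micro-time resolution",
                  "flimr_incompatible_acquisition")
    }
  }
  total <- Reduce(`+`, lapply(images, function(im) im$counts))
  flim_image(total, dt)
}

#' Full-field decay histogram of a FLIM image
#'
#' @param image A [flim_image()] (or list of them, summed first).
#' @return Tibble with `time_ns` and `counts` summed over all pixels.
#' @export
full_field_histogram <- function(image) {
  if (is.list(image) && !inherits(image, "flim_image")) {
    image <- sum_flim_images(image)
  }
  nb <- dim(image$counts)[3]
  cnt <- colSums(matrix(image$counts, ncol = nb))
  tibble::tibble(time_ns = flim_time_axis(image), counts = as.integer(round(cnt)))
}
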