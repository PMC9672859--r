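# Label-mask ingestion, image-moment ellipse shape metrics, and long/short
# axis splitting of nuclear-envelope rings.

#' Segments from a label mask
#'
#' One record per distinct positive label; background is 0. Disconnected
#' pixels sharing a label are merged under one record (labels are taken as
#' curated segment identities, not re-split).
#'
#' @param mask Integer matrix; 0 = background, positive values = segment
#'   labels.
#' @return Tibble with columns `label`, `n_pixels`, `pixels` (list of
#'   two-column row/col matrices, 1-based), `centroid_row`, `centroid_col`.
#' @export
mask_segments <- function(mask) {
  if (!is.matrix(mask) || any(!is.finite(mask)) ||
      any(mask != round(mask)) || any(mask < 0)) {
    abort_flimr("mask must be an integer-valued matrix with 0 background",
                "flimr_format_error")
  }
  labels <- sort(unique(mask[mask > 0]))
  recs <- lapply(labels, function(lb) {
    px <- which(mask == lb, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    tibble::tibble(
      label = as.integer(lb),
      n_pixels = nrow(px),
      pixels = list(px),
      centroid_row = mean(px[, 1]),
      centroid_col = mean(px[, 2])
    )
  })
  if (length(recs) == 0L) {
    return(tibble::tibble(label = integer(), n_pixels = integer(),
                          pixels = list(), centroid_row = numeric(),
                          centroid_col = numeric()))
  }
  dplyr::bind_rows(recs)
}

# Second-central-moment ellipse of a pixel set. Axis lengths follow the
# image-moment convention (full axes = 4 * sqrt(eigenvalue)), under which a
# filled ellipse recovers its own axes. Orientation is the angle of the
# major axis from the image row axis, in (-pi/2, pi/2].
moment_ellipse <- function(px) {
  r <- px[, 1] - mean(px[, 1])
  c <- px[, 2] - mean(px[, 2])
  n <- nrow(px)
  mrr <- sum(r * r) / n
  mcc <- sum(c * c) / n
  mrc <- sum(r * c) / n
  tr <- mrr + mcc
  det <- mrr * mcc - mrc * mrc
  disc <- sqrt(max(tr * tr / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  theta <- 0.5 * atan2(2 * mrc, mrr - mcc)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2), orientation = theta)
}

#' Ellipse-based shape metrics per segment
#'
#' Fits the image-moment ellipse to each segment's pixels and records the
#' major/minor axis lengths, orientation, aspect ratio (major/minor, >= 1)
#' and roundness (minor/major, in (0, 1]). Collinear pixel sets get
#' `aspect_ratio = Inf` and are meant to be QC-rejected downstream. The
#' isoperimetric roundness `4*pi*A/P^2` is available as an alternative
#' `roundness` definition.
#'
#' @param segments Tibble from [mask_segments()].
#' @param min_pixels Minimum pixels for a defined ellipse.
#' @param roundness_method `"axis"` (minor/major, default) or
#'   `"isoperimetric"` (`4*pi*A/P^2` with a 4-neighbour boundary perimeter).
#' @return The input tibble with `major_axis`, `minor_axis`, `orientation`,
#'   `aspect_ratio`, `roundness` columns added.
#' @export
ellipse_shape <- function(segments, min_pixels = 5L,
                          roundness_method = c("axis", "isoperimetric")) {
  roundness_method <- match.arg(roundness_method)
  met <- purrr::map(segments$pixels, function(px) {
    if (nrow(px) < min_pixels) {
      return(list(major = NA_real_, minor = NA_real_, orientation = NA_real_))
    }
    moment_ellipse(px)
  })
  segments$major_axis <- purrr::map_dbl(met, "major")
  segments$minor_axis <- purrr::map_dbl(met, "minor")
  segments$orientation <- purrr::map_dbl(met, "orientation")
  segments$aspect_ratio <- ifelse(segments$minor_axis > 0,
                                  segments$major_axis / segments$minor_axis,
                                  Inf)
  segments$roundness <- if (roundness_method == "axis") {
    ifelse(is.finite(segments$aspect_ratio), 1 / segments$aspect_ratio, 0)
  } else {
    purrr::map_dbl(segments$pixels, iso_roundness)
  }
  segments
}

# Isoperimetric roundness. The raw count of exposed 4-neighbour pixel edges
# measures the staircase (Manhattan) boundary length, which overestimates a
# smooth contour by 4/pi on average over orientations (Cauchy-Crofton), so
# the edge count is scaled by pi/4.
iso_roundness <- function(px) {
  keys <- px[, 1] * 1e6 + px[, 2]
  inside <- function(r, c) (r * 1e6 + c) %in% keys
  edges <- 0L
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; c <- px[i, 2]
    edges <- edges + sum(!inside(c(r - 1, r + 1, r, r), c(c, c, c - 1, c + 1)))
  }
  perim <- edges * pi / 4
  a <- nrow(px)
  min(4 * pi * a / perim^2, 1)
}

#' Split an envelope into long-axis and short-axis arcs
#'
#' Each pixel is assigned by the angle of (pixel - centroid) relative to the
#' segment's major axis: within 45 degrees of the major axis (either end) it
#' belongs to the long-axis arc, otherwise to the short-axis arc. The split
#' is equivalent to comparing the magnitudes of the projections on the major
#' and minor axes, so the two subsets always partition the pixel set.
#'
#' @param segments Tibble from [ellipse_shape()].
#' @param aspect_floor Below this aspect ratio the axes are ill-defined and a
#'   warning is raised (the partition is still returned).
#' @return The tibble with list-columns `pixels_long` and `pixels_short`.
#' @export
split_envelope_axes <- function(segments, aspect_floor = 1.05) {
  if (!"orientation" %in% names(segments)) {
    abort_flimr("run ellipse_shape() before split_envelope_axes()",
                "flimr_invalid_parameter")
  }
  low <- which(is.finite(segments$aspect_ratio) &
                 segments$aspect_ratio < aspect_floor)
  if (length(low) > 0L) {
    rlang::warn(
      sprintf("segment(s) %s have aspect ratio below %.3g; axis split is ill-defined",
              paste(segments$label[low], collapse = ", "), aspect_floor),
      class = "flimr_axes_ill_defined"
    )
  }
  parts <- purrr::pmap(
    list(segments$pixels, segments$orientation,
         segments$centroid_row, segments$centroid_col),
    function(px, th, cr, cc) {
      dr <- px[, 1] - cr
      dc <- px[, 2] - cc
      pu <- dr * cos(th) + dc * sin(th)   # along major axis
      pv <- -dr * sin(th) + dc * cos(th)  # along minor axis
      long <- abs(pu) >= abs(pv)
      list(long = px[long, , drop = FALSE], short = px[!long, , drop = FALSE])
    }
  )
  segments$pixels_long <- purrr::map(parts, "long")
  segments$pixels_short <- purrr::map(parts, "short")
  segments
}

#' Attach per-segment decay histograms from a FLIM image
#'
#' Sums the per-pixel micro-time counts over each segment's pixels.
#'
#' @param segments Tibble with a `pixels` list-column (from
#'   [mask_segments()]).
#' @param image A [flim_image()] or list of timepoint images (summed first).
#' @return The tibble with `histogram` (list of tibbles) and `photon_count`
#'   columns added.
#' @export
attach_histograms <- function(segments, image) {
  if (is.list(image) && !inherits(image, "flim_image")) {
    image <- sum_flim_images(image)
  }
  d <- dim(image$counts)
  nb <- d[3]
  flat <- matrix(image$counts, nrow = d[1] * d[2], ncol = nb)
  taxis <- flim_time_axis(image)
  hists <- purrr::map2(segments$pixels, segments$label, function(px, lb) {
    if (any(px[, 1] < 1 | px[, 1] > d[1] | px[, 2] < 1 | px[, 2] > d[2])) {
      abort_flimr(sprintf("segment %d has pixels outside the image", lb),
                  "flimr_coordinate_error")
    }
    lin <- px[, 1] + (px[, 2] - 1L) * d[1]
    cnt <- colSums(flat[lin, , drop = FALSE])
    tibble::tibble(time_ns = taxis, counts = as.integer(round(cnt)))
  })
  segments$histogram <- hists
  segments$photon_count <- purrr::map_int(hists, ~ sum(.x$counts))
  segments
}
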