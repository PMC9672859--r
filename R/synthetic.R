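# Monte-Carlo generator of TCSPC decays and FLIM scenes with known ground
# truth. The generator is the oracle for every fitting and pipeline test.

#' Ground truth for a simulated TCSPC decay
#'
#' Photon micro-times are generated as a mixture: a fast autofluorescence
#' exponential, a slower sensor-signal exponential (both jittered by a
#' Gaussian instrument response) and a uniform background over the TCSPC
#' window (emulating scattered or ambient light). Defaults are plausible for
#' an mTFP donor system on a 80 MHz-class rig: `tau_auto = 0.4` ns,
#' `tau_signal = 2.8` ns, `sigma = 0.1` ns, 12.5 ns window over 250 bins.
#'
#' @param tau_signal Signal (donor) lifetime in ns.
#' @param tau_auto Autofluorescence lifetime in ns.
#' @param fraction_auto Fraction of photons from the autofluorescence
#'   component.
#' @param background_fraction Fraction of photons arriving uniformly over the
#'   window.
#' @param mu,sigma Gaussian IRF centre and width in ns.
#' @param n_photons Total photons to draw.
#' @param window TCSPC window length in ns.
#' @param n_bins Number of histogram bins over the window.
#' @param wrap `"wrap"` folds photons beyond the window back modulo the
#'   window (repetition-rate wrap-around of long-lived emission); `"clip"`
#'   discards them.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(tau_signal = 2.8, tau_auto = 0.4,
                             fraction_auto = 0, background_fraction = 0,
                             mu = 1.0, sigma = 0.1,
                             n_photons = 10000, window = 12.5,
                             n_bins = 250, wrap = c("wrap", "clip")) {
  wrap <- match.arg(wrap)
  if (tau_signal <= 0 || tau_auto <= 0 || sigma <= 0 || window <= 0) {
    abort_flimr("lifetimes, sigma and window must be positive",
                "flimr_invalid_parameter")
  }
  if (fraction_auto < 0 || background_fraction < 0 ||
      fraction_auto + background_fraction > 1) {
    abort_flimr("component fractions must be in [0,1] and sum to at most 1",
                "flimr_invalid_parameter")
  }
  structure(
    list(tau_signal = tau_signal, tau_auto = tau_auto,
         fraction_auto = fraction_auto,
         background_fraction = background_fraction,
         mu = mu, sigma = sigma, n_photons = as.integer(n_photons),
         window = window, n_bins = as.integer(n_bins), wrap = wrap),
    class = "simulation_truth"
  )
}

#' Sample photon arrival times from a ground truth
#'
#' Each photon picks a component by the truth's fractions; exponential
#' components draw an exponential waiting time plus Gaussian IRF jitter,
#' background photons arrive uniformly over the window. Times outside the
#' window are wrapped modulo the window (default) or discarded.
#'
#' @param truth A [simulation_truth()].
#' @param n Number of photons (defaults to `truth$n_photons`).
#' @param seed Optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is untouched.
#' @return Numeric vector of arrival times in ns within `[0, window)`.
#' @export
sample_photons <- function(truth, n = truth$n_photons, seed = NULL) {
  if (n < 1) abort_flimr("n_photons must be >= 1", "flimr_invalid_parameter")
  draw <- function() {
    u <- stats::runif(n)
    is_auto <- u < truth$fraction_auto
    is_bg <- !is_auto & u < truth$fraction_auto + truth$background_fraction
    t <- numeric(n)
    n_auto <- sum(is_auto)
    n_bg <- sum(is_bg)
    n_sig <- n - n_auto - n_bg
    if (n_auto > 0) {
      t[is_auto] <- stats::rexp(n_auto, rate = 1 / truth$tau_auto) +
        stats::rnorm(n_auto, truth$mu, truth$sigma)
    }
    if (n_sig > 0) {
      sig <- !is_auto & !is_bg
      t[sig] <- stats::rexp(n_sig, rate = 1 / truth$tau_signal) +
        stats::rnorm(n_sig, truth$mu, truth$sigma)
    }
    if (n_bg > 0) t[is_bg] <- stats::runif(n_bg, 0, truth$window)
    if (truth$wrap == "wrap") {
      t <- t %% truth$window
    } else {
      t <- t[t >= 0 & t < truth$window]
    }
    t
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw)
}

# Minimal local with_seed (avoids a hard dependency in the hot path):
# evaluates fn() under set.seed(seed) and restores the prior RNG state.
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Bin photon arrival times into a decay histogram
#'
#' @param times Numeric arrival times in ns.
#' @param grid Either a [simulation_truth()] (its window and bin count are
#'   used) or a list/vector interface: `n_bins` and `window`.
#' @param n_bins,window Used when `grid` is not supplied.
#' @return Tibble with `time_ns` (bin centres) and integer `counts`.
#' @export
bin_photons <- function(times, grid = NULL, n_bins = NULL, window = NULL) {
  if (inherits(grid, "simulation_truth")) {
    n_bins <- grid$n_bins
    window <- grid$window
  }
  if (is.null(n_bins) || is.null(window)) {
    abort_flimr("bin_photons needs n_bins and window (or a simulation_truth)",
                "flimr_invalid_parameter")
  }
  dt <- window / n_bins
  idx <- floor(times / dt) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  tibble::tibble(
    time_ns = (seq_len(n_bins) - 0.5) * dt,
    counts = tabulate(idx, nbins = n_bins)
  )
}

#' Simulated decay histogram in one call
#'
#' Convenience wrapper: [sample_photons()] then [bin_photons()].
#'
#' @inheritParams sample_photons
#' @return Tibble with `time_ns` and `counts`.
#' @export
simulate_decay <- function(truth, n = truth$n_photons, seed = NULL) {
  bin_photons(sample_photons(truth, n = n, seed = seed), truth)
}

#' Configure a synthetic FLIM scene
#'
#' A scene is a 2D field with elliptical-ring regions of interest standing in
#' for nuclear envelopes, each with its own decay ground truth and photon
#' budget, plus a field-background truth for all non-ROI pixels, acquired
#' over `n_timepoints` frames (budgets split evenly, remainders to the
#' earliest frames, so totals are conserved exactly).
#'
#' @param dims Image dimensions `c(rows, cols)`.
#' @param rois Tibble with one row per ring ROI: `label`, `center_row`,
#'   `center_col`, `semi_major`, `semi_minor`, `orientation` (radians from
#'   the row axis), `thickness` (px), `n_photons`, and optionally per-ROI
#'   `tau_signal`, `tau_auto`, `fraction_auto`, `background_fraction`.
#' @param field_truth A [simulation_truth()] for non-ROI pixels (its
#'   `n_photons` is the field budget); `NULL` for a dark field.
#' @param base_truth Template [simulation_truth()] supplying IRF, window and
#'   binning shared by all ROIs.
#' @param n_timepoints Number of acquisition frames (default 6).
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(dims, rois, field_truth = NULL,
                         base_truth = simulation_truth(),
                         n_timepoints = 6L) {
  req <- c("label", "center_row", "center_col", "semi_major", "semi_minor",
           "orientation", "thickness", "n_photons")
  missing_cols <- setdiff(req, names(rois))
  if (length(missing_cols) > 0L) {
    abort_flimr(sprintf("rois is missing columns: %s",
                        paste(missing_cols, collapse = ", ")),
                "flimr_config_error")
  }
  if (anyDuplicated(rois$label)) {
    abort_flimr("ROI labels must be unique", "flimr_config_error")
  }
  structure(
    list(dims = as.integer(dims), rois = tibble::as_tibble(rois),
         field_truth = field_truth, base_truth = base_truth,
         n_timepoints = as.integer(n_timepoints)),
    class = "scene_config"
  )
}

# Pixels of an elliptical ring (outer minus inner ellipse), row/col matrix.
ring_pixels <- function(dims, center_row, center_col, semi_major, semi_minor,
                        orientation, thickness) {
  a <- semi_major
  b <- semi_minor
  ai <- max(a - thickness, 0)
  bi <- max(b - thickness, 0)
  rr <- max(1L, floor(center_row - a)):min(dims[1], ceiling(center_row + a))
  cc <- max(1L, floor(center_col - a)):min(dims[2], ceiling(center_col + a))
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - center_row
  dc <- g$col - center_col
  pu <- dr * cos(orientation) + dc * sin(orientation)
  pv <- -dr * sin(orientation) + dc * cos(orientation)
  r_out <- (pu / a)^2 + (pv / b)^2
  inside_out <- r_out <= 1
  inside_in <- if (ai > 0 && bi > 0) (pu / ai)^2 + (pv / bi)^2 < 1 else FALSE
  keep <- inside_out & !inside_in
  as.matrix(g[keep, c("row", "col"), drop = FALSE])
}

# Column value if present, else default (tibbles warn on absent `$`).
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

roi_truth <- function(roi, base) {
  simulation_truth(
    tau_signal = col_or(roi, "tau_signal", base$tau_signal),
    tau_auto = col_or(roi, "tau_auto", base$tau_auto),
    fraction_auto = col_or(roi, "fraction_auto", base$fraction_auto),
    background_fraction = col_or(roi, "background_fraction",
                                 base$background_fraction),
    mu = base$mu, sigma = base$sigma,
    n_photons = roi$n_photons,
    window = base$window, n_bins = base$n_bins, wrap = base$wrap
  )
}

# Split a budget across frames: even shares, remainder to the first frames.
split_budget <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + (seq_len(k) <= extra)
}

#' Simulate a multi-timepoint FLIM scene
#'
#' Fills each ring ROI with photons drawn from its ground truth and non-ROI
#' pixels from the field-background truth; pixels within an ROI are chosen
#' uniformly. Returns one [flim_image()] per timepoint, the label mask and a
#' truth table.
#'
#' @param scene A [scene_config()].
#' @param seed Integer seed; the scene is a pure function of (scene, seed).
#' @return List with `images` (list of `flim_image`), `mask` (integer
#'   matrix), `truth` (tibble of per-ROI ground truth and budgets), and
#'   `scene`.
#' @export
simulate_scene <- function(scene, seed = 1L) {
  withr_seed(seed, function() {
    dims <- scene$dims
    base <- scene$base_truth
    nb <- base$n_bins
    npx <- prod(dims)
    rois <- scene$rois
    mask <- matrix(0L, dims[1], dims[2])
    pix_list <- vector("list", nrow(rois))
    for (i in seq_len(nrow(rois))) {
      px <- ring_pixels(dims, rois$center_row[i], rois$center_col[i],
                        rois$semi_major[i], rois$semi_minor[i],
                        rois$orientation[i], rois$thickness[i])
      if (nrow(px) == 0L) {
        abort_flimr(sprintf("ROI %d has no pixels inside the image",
                            rois$label[i]), "flimr_config_error")
      }
      lin <- px[, 1] + (px[, 2] - 1L) * dims[1]
      if (any(mask[lin] != 0L)) {
        abort_flimr("ROIs overlap", "flimr_config_error")
      }
      mask[lin] <- as.integer(rois$label[i])
      pix_list[[i]] <- lin
    }
    field_pix <- which(mask == 0L)
    images <- vector("list", scene$n_timepoints)
    budgets <- lapply(seq_len(nrow(rois)), function(i) {
      split_budget(rois$n_photons[i], scene$n_timepoints)
    })
    field_budget <- if (!is.null(scene$field_truth)) {
      split_budget(scene$field_truth$n_photons, scene$n_timepoints)
    } else {
      integer(scene$n_timepoints)
    }
    dt <- base$window / nb
    for (tp in seq_len(scene$n_timepoints)) {
      all_idx <- vector("list", nrow(rois) + 1L)
      for (i in seq_len(nrow(rois))) {
        np <- budgets[[i]][tp]
        if (np == 0L) next
        tr <- roi_truth(rois[i, ], base)
        times <- sample_photons(tr, n = np)
        bins <- floor(times / dt) + 1
        keep <- bins >= 1 & bins <= nb
        pix <- pix_list[[i]][sample.int(length(pix_list[[i]]), sum(keep),
                                        replace = TRUE)]
        all_idx[[i]] <- (pix - 1) * nb + bins[keep]
      }
      if (field_budget[tp] > 0L && length(field_pix) > 0L) {
        times <- sample_photons(scene$field_truth, n = field_budget[tp])
        bins <- floor(times / dt) + 1
        keep <- bins >= 1 & bins <= nb
        pix <- field_pix[sample.int(length(field_pix), sum(keep),
                                    replace = TRUE)]
        all_idx[[nrow(rois) + 1L]] <- (pix - 1) * nb + bins[keep]
      }
      idx <- unlist(all_idx)
      tab <- tabulate(idx, nbins = npx * nb)
      # counts cube [rows, cols, bins] from the (pixel, bin) index
      cube <- aperm(array(tab, dim = c(nb, dims[1], dims[2])), c(2, 3, 1))
      images[[tp]] <- flim_image(cube, dt = dt)
    }
    truth <- dplyr::mutate(
      rois,
      tau_signal = col_or(rois, "tau_signal", base$tau_signal),
      tau_auto = col_or(rois, "tau_auto", base$tau_auto),
      fraction_auto = col_or(rois, "fraction_auto", base$fraction_auto),
      background_fraction = col_or(rois, "background_fraction",
                                   base$background_fraction),
      n_pixels = vapply(pix_list, length, integer(1))
    )
    list(images = images, mask = mask, truth = truth, scene = scene,
         seed = seed)
  })
}

#' A ready-made scene with a monotone lifetime gradient
#'
#' Lays out `n_rings` elliptical rings on a grid with signal lifetimes
#' spanning `tau_range`, emulating a proximodistal tension gradient across
#' nuclear envelopes.
#'
#' @param n_rings Number of ring ROIs.
#' @param photons_per_ring Photon budget per ROI.
#' @param tau_range Range of signal lifetimes (ns) across the rings.
#' @param dims Image dimensions.
#' @param base_truth Shared IRF/window/binning template.
#' @param n_timepoints Acquisition frames.
#' @return A [scene_config()].
#' @export
gradient_scene <- function(n_rings = 10, photons_per_ring = 10000,
                           tau_range = c(2.0, 3.2), dims = c(96, 96),
                           base_truth = simulation_truth(fraction_auto = 0.2),
                           n_timepoints = 6L) {
  per_row <- ceiling(sqrt(n_rings))
  spacing_r <- dims[1] / per_row
  spacing_c <- dims[2] / per_row
  ix <- seq_len(n_rings)
  rows <- ((ix - 1) %/% per_row + 0.5) * spacing_r
  cols <- ((ix - 1) %% per_row + 0.5) * spacing_c
  rad <- 0.32 * min(spacing_r, spacing_c)
  rois <- tibble::tibble(
    label = ix,
    center_row = rows, center_col = cols,
    semi_major = rad, semi_minor = 0.7 * rad,
    orientation = (ix %% 4) * pi / 4 - pi / 4,
    thickness = max(2, 0.3 * rad),
    n_photons = as.integer(photons_per_ring),
    tau_signal = seq(tau_range[1], tau_range[2], length.out = n_rings)
  )
  scene_config(dims, rois, base_truth = base_truth,
               n_timepoints = n_timepoints)
}
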