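# Label-mask ingestion, moment-ellipse shape metrics, axis splitting.

test_that("labels become segment records with exact pixel sets", {
  mask <- matrix(0L, 12, 12)
  mask[4:8, 5:9] <- 3L
  segs <- mask_segments(mask)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_pixels, 25L)
  expect_equal(segs$centroid_row, 6)
  expect_equal(segs$centroid_col, 7)
  # empty mask
  expect_equal(nrow(mask_segments(matrix(0L, 5, 5))), 0L)
  # non-integer mask
  expect_error(mask_segments(matrix(0.5, 3, 3)), class = "flimr_format_error")
})

test_that("pixel sets of a random multi-label mask tile the support", {
  set.seed(7)
  mask <- matrix(sample(0:4, 400, replace = TRUE), 20, 20)
  segs <- mask_segments(mask)
  rebuilt <- matrix(0L, 20, 20)
  for (i in seq_len(nrow(segs))) {
    px <- segs$pixels[[i]]
    rebuilt[px] <- segs$label[i]
  }
  expect_identical(rebuilt, matrix(as.integer(mask), 20, 20))
})

test_that("moment ellipse recovers disc and ellipse shapes", {
  disc <- mask_segments(raster_ellipse(50, 50, 25, 25, 20, 20))
  disc <- ellipse_shape(disc)
  expect_lt(abs(disc$aspect_ratio - 1), 0.05)
  ell <- ellipse_shape(mask_segments(raster_ellipse(60, 60, 30, 30, 10, 20)))
  expect_lt(abs(ell$aspect_ratio - 2), 0.1)
  # 40 px across the columns: orientation perpendicular to the row axis
  expect_lt(abs(abs(ell$orientation) - pi / 2), 0.05)
  expect_equal(ell$aspect_ratio * ell$roundness, 1, tolerance = 1e-9)
})

test_that("shape metrics are rotation-equivariant and translation-invariant", {
  th <- 30 * pi / 180
  rot <- ellipse_shape(mask_segments(raster_ellipse(80, 80, 40, 40, 20, 10, th)))
  expect_lt(abs(rot$aspect_ratio - 2), 0.1)
  expect_lt(abs(rot$orientation - th), 3 * pi / 180)
  shifted <- ellipse_shape(mask_segments(raster_ellipse(80, 80, 55, 23, 20, 10, th)))
  expect_equal(shifted$aspect_ratio, rot$aspect_ratio, tolerance = 0.02)
  expect_equal(shifted$orientation, rot$orientation, tolerance = 0.02)
})

test_that("isoperimetric roundness distinguishes discs from elongated shapes", {
  disc <- mask_segments(raster_ellipse(50, 50, 25, 25, 18, 18))
  r_disc <- ellipse_shape(disc, roundness_method = "isoperimetric")$roundness
  expect_gt(r_disc, 0.9)
  ell <- mask_segments(raster_ellipse(70, 70, 35, 35, 28, 7))
  r_ell <- ellipse_shape(ell, roundness_method = "isoperimetric")$roundness
  expect_lt(r_ell, r_disc - 0.2)
})

test_that("degenerate pixel sets flag an infinite aspect ratio", {
  mask <- matrix(0L, 10, 10)
  mask[5, 2:8] <- 1L  # collinear
  segs <- ellipse_shape(mask_segments(mask))
  expect_true(is.infinite(segs$aspect_ratio))
  expect_equal(segs$roundness, 0)
})

test_that("axis splitting partitions by angle to the major axis", {
  ring <- raster_ellipse(80, 80, 40, 40, 30, 15) -
    raster_ellipse(80, 80, 40, 40, 26, 11)
  segs <- split_envelope_axes(ellipse_shape(mask_segments(ring)))
  px_l <- segs$pixels_long[[1]]
  px_s <- segs$pixels_short[[1]]
  # partition: union is the original set, intersection empty
  all_px <- rbind(px_l, px_s)
  orig <- segs$pixels[[1]]
  expect_equal(nrow(all_px), nrow(orig))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_setequal(key(all_px), key(orig))
  expect_length(intersect(key(px_l), key(px_s)), 0L)
  # per-pixel angle oracle: the 40x20 ellipse is axis-aligned along columns
  th <- segs$orientation
  cr <- segs$centroid_row
  cc <- segs$centroid_col
  ang <- function(px) {
    dr <- px[, 1] - cr
    dc <- px[, 2] - cc
    a <- atan2(-dr * sin(th) + dc * cos(th), dr * cos(th) + dc * sin(th))
    pmin(abs(a), pi - abs(a))  # angle to the major axis, either end
  }
  expect_true(all(ang(px_l) <= pi / 4 + 1e-9))
  expect_true(all(ang(px_s) >= pi / 4 - 1e-9))
})

test_that("a circle splits into nearly equal arcs with a warning", {
  ring <- raster_ellipse(90, 90, 45, 45, 34, 34) -
    raster_ellipse(90, 90, 45, 45, 28, 28)
  segs <- ellipse_shape(mask_segments(ring))
  expect_warning(out <- split_envelope_axes(segs),
                 class = "flimr_axes_ill_defined")
  n_l <- nrow(out$pixels_long[[1]])
  n_s <- nrow(out$pixels_short[[1]])
  expect_lt(abs(n_l - n_s) / (n_l + n_s), 0.02)
})

test_that("axis splitting partitions 100 random synthetic rings", {
  set.seed(9)
  for (i in 1:100) {
    a <- runif(1, 8, 20)
    b <- runif(1, 5, a)
    th <- runif(1, -pi / 2, pi / 2)
    ring <- raster_ellipse(48, 48, 24, 24, a, b, th) -
      raster_ellipse(48, 48, 24, 24, max(a - 4, 2), max(b - 4, 1.5), th)
    segs <- suppressWarnings(
      split_envelope_axes(ellipse_shape(mask_segments(ring)))
    )
    expect_equal(nrow(segs$pixels_long[[1]]) + nrow(segs$pixels_short[[1]]),
                 segs$n_pixels)
    expect_gte(segs$aspect_ratio, 1)
    expect_true(segs$roundness > 0 && segs$roundness <= 1)
  }
})

test_that("histograms attach by exact per-pixel recount", {
  cube <- random_cube(8, 9, 16, seed = 21)
  img <- flim_image(cube, dt = 0.05)
  mask <- matrix(0L, 8, 9)
  mask[2, 3] <- 1L
  mask[5:6, 4:5] <- 2L
  segs <- attach_histograms(mask_segments(mask), img)
  # single-pixel segment equals that pixel's micro-time vector
  expect_equal(segs$histogram[[1]]$counts, as.integer(cube[2, 3, ]))
  # brute-force recount oracle
  manual <- rep(0L, 16)
  for (r in 5:6) for (c in 4:5) manual <- manual + cube[r, c, ]
  expect_equal(segs$histogram[[2]]$counts, as.integer(manual))
  expect_equal(segs$photon_count[2], sum(manual))
  # out-of-bounds pixels are a coordinate error naming the segment
  bad <- segs
  bad$pixels[[1]] <- matrix(c(9L, 3L), 1, 2,
                            dimnames = list(NULL, c("row", "col")))
  expect_error(attach_histograms(bad, img), "segment 1",
               class = "flimr_coordinate_error")
})
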