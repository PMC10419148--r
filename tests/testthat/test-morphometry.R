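test_that("phase converts to optical path length by phi*lambda/(2*pi)", {
  expect_identical(phase_to_opl(0, 640), 0)
  expect_equal(phase_to_opl(2 * pi, 640), 0.640, tolerance = 1e-12)
  expect_equal(phase_to_opl(1, 640), 0.640 / (2 * pi), tolerance = 1e-12)
  expect_error(phase_to_opl(1, -5))
})

test_that("uniform-phase disc has exact symmetric descriptors", {
  mask <- raster_disc(14, side = 41)
  phase <- matrix(0, 41, 41)
  phase[mask] <- 1.0
  f <- compute_features(phase, mask, 0.24)
  expect_identical(f$eccentricity, 0)
  expect_identical(f$elongation_ratio, 1)
  expect_equal(f$mean_phase, 1.0)
  expect_identical(f$std_phase, 0)
  expect_identical(f$max_phase_gradient, 0)
  expect_identical(f$area_um2, sum(mask) * 0.24^2)
  expect_equal(f$mean_opl_um, phase_to_opl(1, 640))
})

test_that("a 2:1 ellipse yields eccentricity sqrt(3)/2 and elongation 2", {
  mask <- raster_ellipse(60, 30, theta = 0.4, side = 141)
  phase <- matrix(0, 141, 141)
  phase[mask] <- 0.8
  f <- compute_features(phase, mask, 0.1)
  expect_equal(f$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  expect_equal(f$elongation_ratio, 2, tolerance = 0.02)
})

test_that("moment descriptors agree with the analytic ellipse values", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 25, 60)
    ratio <- runif(1, 1.05, 3.5)
    b <- a / ratio
    th <- runif(1, 0, pi)
    mask <- raster_ellipse(a, b, th, side = 141)
    phase <- matrix(0, 141, 141)
    phase[mask] <- 1
    f <- compute_features(phase, mask, 0.1)
    expect_equal(f$eccentricity, sqrt(1 - (b / a)^2), tolerance = 0.02)
    expect_equal(f$elongation_ratio, ratio, tolerance = 0.02 * ratio)
  }
})

test_that("descriptors are stable under rotation", {
  f0 <- compute_features(matrix(1, 141, 141), raster_ellipse(50, 25, 0, 141), 0.1)
  f30 <- compute_features(matrix(1, 141, 141),
                          raster_ellipse(50, 25, pi / 6, 141), 0.1)
  expect_lt(abs(f0$eccentricity - f30$eccentricity), 0.03)
  expect_lt(abs(f0$elongation_ratio - f30$elongation_ratio), 0.03 * 2)
})

test_that("doubling the pixel pitch rescales area and perimeter", {
  mask <- raster_ellipse(20, 12, 0.7, side = 61)
  phase <- matrix(runif(61 * 61), 61, 61)
  f1 <- compute_features(phase, mask, 0.2)
  f2 <- compute_features(phase, mask, 0.4)
  expect_equal(f2$area_um2, 4 * f1$area_um2)
  expect_equal(f2$perimeter_um, 2 * f1$perimeter_um)
})

test_that("masked phase statistics equal a naive loop oracle", {
  set.seed(21)
  side <- 31
  mask <- raster_disc(10, side)
  phase <- matrix(rnorm(side^2, 1, 0.3), side, side)
  f <- compute_features(phase, mask, 0.24)
  vals <- c()
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if (mask[i, j]) vals <- c(vals, phase[i, j])
    }
  }
  m <- sum(vals) / length(vals)
  m2 <- sum((vals - m)^2) / length(vals)
  expect_equal(f$mean_phase, m)
  expect_equal(f$std_phase, sqrt(m2))
  expect_equal(f$max_phase, max(vals))
  expect_equal(f$min_phase, min(vals))
  expect_equal(f$median_phase, median(vals))
  expect_equal(f$p25_phase, unname(quantile(vals, 0.25)))
  expect_equal(f$p75_phase, unname(quantile(vals, 0.75)))
  expect_equal(f$skewness_phase, sum((vals - m)^3) / length(vals) / m2^1.5)
  expect_equal(f$kurtosis_phase, sum((vals - m)^4) / length(vals) / m2^2)
  opl <- sort(phase_to_opl(vals, 640), decreasing = TRUE)
  expect_equal(f$top25_opl_um, mean(opl[1:ceiling(length(opl) / 4)]))
  expect_equal(f$integrated_opl_um3, sum(opl) * 0.24^2)
})

test_that("a linear phase ramp has uniform interior gradient magnitude", {
  side <- 41
  slope <- 0.05  # rad per pixel along x
  phase <- matrix(rep(slope * seq_len(side), each = side), side, side,
                  byrow = TRUE)
  mask <- raster_disc(12, side)
  f <- compute_features(phase, mask, 0.25)
  expect_equal(f$max_phase_gradient, slope / 0.25, tolerance = 1e-10)
  expect_equal(f$mean_phase_gradient, slope / 0.25, tolerance = 1e-10)
  expect_equal(f$std_phase_gradient, 0, tolerance = 1e-10)
})

test_that("feature extraction rejects degenerate inputs", {
  expect_error(compute_features(matrix(1, 5, 5), matrix(FALSE, 5, 5), 0.24),
               class = "sicklecyto_unsegmentable")
  ph <- matrix(1, 5, 5)
  ph[2, 2] <- NA
  expect_error(compute_features(ph, matrix(TRUE, 5, 5), 0.24), "finite")
})

test_that("segmentation recovers the generator mask and handles failures", {
  img <- make_normal_phase_image(
    cell_shape("normal_like", radius_um = 3.2, elongation = 1.2,
               peak_phase_rad = 1.3, dimple_depth = 0.4),
    imaging_config(), noise = FALSE
  )
  expect_identical(segment_cell(img$phase), img$mask)
  expect_error(segment_cell(matrix(0, 32, 32)),
               class = "sicklecyto_unsegmentable")
})

test_that("segmentation keeps only the largest of two cells", {
  side <- 64
  v <- seq_len(side)
  big <- outer(v, v, function(y, x) (x - 20)^2 + (y - 32)^2) <= 12^2
  small <- outer(v, v, function(y, x) (x - 50)^2 + (y - 32)^2) <= 6^2
  phase <- matrix(0, side, side)
  phase[big] <- 1
  phase[small] <- 1
  mask <- segment_cell(phase, 0.5)
  expect_identical(mask, big)
})
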