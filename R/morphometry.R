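#' The 25 morphological parameter names
#'
#' Shape descriptors come from the cell mask, phase statistics from the
#' masked phase values, optical-path-length (OPL) descriptors from the
#' phase-to-OPL conversion, and gradient statistics from central-difference
#' spatial gradients of the phase map.
#'
#' @return Character vector of length 25.
#' @export
feature_names <- function() {
  c(
    "area_um2", "perimeter_um", "circularity", "eccentricity",
    "elongation_ratio", "solidity", "extent", "equivalent_diameter_um",
    "aspect_ratio_bbox", "perimeter_area_ratio",
    "mean_phase", "max_phase", "min_phase", "std_phase", "median_phase",
    "p25_phase", "p75_phase", "skewness_phase", "kurtosis_phase",
    "integrated_opl_um3", "mean_opl_um", "top25_opl_um",
    "max_phase_gradient", "mean_phase_gradient", "std_phase_gradient"
  )
}

#' Convert phase to optical path length
#'
#' The standard quantitative-phase relation `OPL = phi * lambda / (2*pi)`,
#' returned in micrometres.
#'
#' @param phase_rad Phase in radians (vector or matrix).
#' @param wavelength_nm Illumination wavelength, nanometres.
#' @return OPL in micrometres, same shape as `phase_rad`.
#' @examples
#' phase_to_opl(2 * pi, 640)  # 0.640 um
#' @export
phase_to_opl <- function(phase_rad, wavelength_nm = 640) {
  stopifnot(wavelength_nm > 0)
  phase_rad * (wavelength_nm * 1e-3) / (2 * pi)
}

# Perimeter from the crack boundary (pixel-edge transitions between mask
# and background, counted horizontally and vertically), scaled by pi/4.
# The crack length of a convex raster shape is its L1 perimeter; pi/4
# maps it to the Euclidean perimeter with little orientation anisotropy
# (a rasterized disc of radius r gets 8r * pi/4 = 2*pi*r exactly).
mask_perimeter_px <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2, nc + 2)
  m[2:(nr + 1), 2:(nc + 1)] <- mask
  h <- sum(xor(m[, -1], m[, -(nc + 2)]))
  v <- sum(xor(m[-1, ], m[-(nr + 2), ]))
  (h + v) * pi / 4
}

# Lattice-polygon area of the convex hull of mask pixel centres, using
# Pick's theorem (interior + boundary/2 - 1 lattice points => area), so a
# convex raster shape gets solidity ~= 1 instead of > 1.
hull_area_px <- function(xy) {
  h <- grDevices::chull(xy)
  if (length(h) < 3) {
    return(nrow(xy))
  }
  pts <- xy[h, , drop = FALSE]
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  shoelace <- abs(sum(x * yn - xn * y)) / 2
  boundary <- sum(mapply(function(dx, dy) {
    if (dx == 0 && dy == 0) 0 else gcd_int(abs(dx), abs(dy))
  }, xn - x, yn - y))
  shoelace + boundary / 2 + 1
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b; b <- a %% b; a <- t
  }
  a
}

# Gradient magnitude of the phase map in rad/um: central differences in
# the interior, one-sided at the image borders.
phase_gradient_magnitude <- function(phase, pitch) {
  nr <- nrow(phase); nc <- ncol(phase)
  gx <- (phase[, c(2:nc, nc)] - phase[, c(1, 1:(nc - 1))])
  gy <- (phase[c(2:nr, nr), ] - phase[c(1, 1:(nr - 1)), ])
  denx <- matrix(2, nr, nc); denx[, c(1, nc)] <- 1
  deny <- matrix(2, nr, nc); deny[c(1, nr), ] <- 1
  sqrt((gx / (denx * pitch))^2 + (gy / (deny * pitch))^2)
}

# Pixels whose 4-neighbourhood lies entirely inside the mask.
mask_interior <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-nr, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -nc, drop = FALSE])
  mask & up & dn & lf & rt
}

#' Extract the 25 morphological parameters of one cell
#'
#' Shape descriptors are computed from the second central moments of the
#' mask pixel coordinates (with the 1/12 pixel-variance correction):
#' `eccentricity = c/a` where `c` is the half inter-focal distance and `a`
#' the semi-major axis of the moment-equivalent ellipse, and
#' `elongation_ratio = a/b`. Phase statistics use masked pixels only;
#' `top25_opl_um` is the mean of the top quartile of per-pixel OPL within
#' the mask; gradient statistics use the gradient-magnitude map restricted
#' to interior mask pixels (pixels whose 4-neighbours are all masked), so
#' the mask edge step does not dominate them.
#'
#' @param phase Phase matrix, radians.
#' @param mask Logical matrix of the same shape (non-empty).
#' @param pixel_pitch_um Pixel pitch, micrometres.
#' @param wavelength_nm Wavelength for the OPL conversion, nanometres.
#' @return A one-row tibble with the 25 columns of [feature_names()].
#' @examples
#' img <- make_normal_phase_image(cell_shape("normal_like"),
#'                                imaging_config(), noise = FALSE)
#' compute_features(img$phase, img$mask, 0.24)
#' @export
compute_features <- function(phase, mask, pixel_pitch_um,
                             wavelength_nm = 640) {
  as_tibble(as.list(compute_features_vec(phase, mask, pixel_pitch_um,
                                         wavelength_nm)))
}

compute_features_vec <- function(phase, mask, pixel_pitch_um,
                                 wavelength_nm = 640) {
  if (!is.logical(mask)) mask <- mask > 0
  stopifnot(identical(dim(phase), dim(mask)))
  if (!any(mask)) {
    abort("unsegmentable cell: empty mask", class = "sicklecyto_unsegmentable")
  }
  if (!all(is.finite(phase))) {
    abort("phase image contains non-finite values")
  }
  p <- pixel_pitch_um
  idx <- which(mask, arr.ind = TRUE)
  n_px <- nrow(idx)
  x <- idx[, 2]; y <- idx[, 1]

  area <- n_px * p^2
  interior <- mask_interior(mask)
  perimeter <- mask_perimeter_px(mask) * p

  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  common <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- (mxx + myy) / 2 + common
  l2 <- max((mxx + myy) / 2 - common, 1e-12)
  eccentricity <- sqrt(max(0, 1 - l2 / l1))
  eccentricity <- min(eccentricity, 1 - 1e-12)
  elongation <- sqrt(l1 / l2)

  bw <- diff(range(x)) + 1
  bh <- diff(range(y)) + 1

  vals <- phase[mask]
  m <- mean(vals)
  cen <- vals - m
  m2 <- mean(cen^2)
  skew <- if (m2 > 1e-12) mean(cen^3) / m2^1.5 else 0
  kurt <- if (m2 > 1e-12) mean(cen^4) / m2^2 else 0

  opl <- phase_to_opl(vals, wavelength_nm)
  n_top <- ceiling(length(opl) / 4)
  top25 <- mean(sort(opl, decreasing = TRUE)[seq_len(n_top)])

  grad <- phase_gradient_magnitude(phase, p)
  gvals <- if (any(interior)) grad[interior] else grad[mask]

  c(
    area_um2 = area,
    perimeter_um = perimeter,
    circularity = 4 * pi * area / perimeter^2,
    eccentricity = eccentricity,
    elongation_ratio = elongation,
    solidity = min(1, n_px / hull_area_px(cbind(x, y))),
    extent = n_px / (bw * bh),
    equivalent_diameter_um = 2 * sqrt(area / pi),
    aspect_ratio_bbox = max(bw, bh) / min(bw, bh),
    perimeter_area_ratio = perimeter / area,
    mean_phase = m,
    max_phase = max(vals),
    min_phase = min(vals),
    std_phase = sqrt(m2),
    median_phase = median(vals),
    p25_phase = unname(quantile(vals, 0.25)),
    p75_phase = unname(quantile(vals, 0.75)),
    skewness_phase = skew,
    kurtosis_phase = kurt,
    integrated_opl_um3 = sum(opl) * p^2,
    mean_opl_um = mean(opl),
    top25_opl_um = top25,
    max_phase_gradient = max(gvals),
    mean_phase_gradient = mean(gvals),
    std_phase_gradient = sd_pop(gvals)
  )
}

sd_pop <- function(v) {
  sqrt(mean((v - mean(v))^2))
}

#' Extract features for a table of cells
#'
#' Maps [compute_features()] over the `phase`/`mask` list-columns of a
#' cell-record tibble (as produced by [generate_sample()] or
#' [read_study()]) and binds the 25 feature columns to the metadata.
#'
#' @param cells Tibble with list-columns `phase` and `mask`.
#' @param pixel_pitch_um Pixel pitch, micrometres.
#' @param wavelength_nm Wavelength for OPL conversion, nanometres.
#' @param keep_images Keep the `phase`/`mask` list-columns in the result?
#'   Default drops them (feature tables of 10^4-10^5 cells stay small).
#' @return A tibble: cell metadata plus the 25 feature columns.
#' @export
cell_features <- function(cells, pixel_pitch_um = 0.24, wavelength_nm = 640,
                          keep_images = FALSE) {
  stopifnot(all(c("phase", "mask") %in% names(cells)))
  mat <- vapply(
    seq_len(nrow(cells)),
    function(i) compute_features_vec(cells$phase[[i]], cells$mask[[i]],
                                     pixel_pitch_um, wavelength_nm),
    numeric(25)
  )
  feats <- as_tibble(as.data.frame(t(mat)))
  meta <- if (keep_images) {
    cells
  } else {
    dplyr::select(cells, -"phase", -"mask")
  }
  dplyr::bind_cols(meta, feats)
}

#' Segment the cell in a phase image
#'
#' Thresholds the phase map at a fraction of its maximum, keeps the
#' largest 4-connected component and fills its holes (the central dimple
#' of a discocyte must belong to the cell).
#'
#' @param phase Phase matrix, radians.
#' @param rel_threshold Fraction of the maximum phase used as threshold,
#'   in (0, 1).
#' @return Logical mask matrix.
#' @examples
#' img <- make_normal_phase_image(cell_shape("normal_like"),
#'                                imaging_config(), noise = FALSE)
#' identical(segment_cell(img$phase), img$mask)
#' @export
segment_cell <- function(phase, rel_threshold = 0.05) {
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  mx <- max(phase)
  bin <- phase > rel_threshold * mx
  if (mx <= 0 || !any(bin)) {
    abort("unsegmentable image: no pixel above threshold",
          class = "sicklecyto_unsegmentable")
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(lab)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  comp <- lab == keep
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  EBImage::imageData(filled) > 0
}
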