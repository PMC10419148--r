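# Core rasterizer shared by the normal and sickled generators.
#
# Cell-frame coordinates (micrometres, origin at the cell centre) are
# rotated by `theta`, offset by `center_um`, and mapped to a normalized
# elliptical radius r with semi-axes a = R*sqrt(e), b = R/sqrt(e) (area of
# the footprint is preserved under elongation). The crescent bend displaces
# the minor-axis coordinate by curvature * x^2 / a, recentred so the cell
# stays inside the frame. Phase profile:
#   phi(r) = peak * sqrt(max(0, 1 - r^2)) * (1 - dimple * exp(-4 r^2))
render_phase_image <- function(shape, imaging, theta = 0,
                               center_um = c(0, 0), noise = TRUE) {
  side <- imaging$image_side
  p <- imaging$pixel_pitch_um
  v <- (seq_len(side) - (side + 1) / 2) * p
  X <- matrix(v, side, side, byrow = TRUE) - center_um[1]
  Y <- matrix(v, side, side) - center_um[2]
  ct <- cos(theta); st <- sin(theta)
  xr <- ct * X + st * Y
  yr <- -st * X + ct * Y
  a <- shape$radius_um * sqrt(shape$elongation)
  b <- shape$radius_um / sqrt(shape$elongation)
  if (shape$curvature > 0) {
    yr <- yr - shape$curvature * xr^2 / a + shape$curvature * a / 3
  }
  r2 <- (xr / a)^2 + (yr / b)^2
  base <- shape$peak_phase_rad * sqrt(pmax(1 - r2, 0))
  phase0 <- base * (1 - shape$dimple_depth * exp(-4 * r2))
  mask <- phase0 > 0.05 * shape$peak_phase_rad
  if (any(mask[1, ]) || any(mask[side, ]) ||
      any(mask[, 1]) || any(mask[, side])) {
    abort(sprintf(
      "geometry overflow: cell footprint (radius %.2f um, elongation %.2f) exceeds the %d x %d px frame",
      shape$radius_um, shape$elongation, side, side
    ), class = "sicklecyto_geometry_overflow")
  }
  if (!any(mask)) {
    abort("degenerate geometry: empty cell mask")
  }
  phase <- phase0
  if (noise && imaging$background_phase_sd > 0) {
    phase <- phase + matrix(
      rnorm(side * side, 0, imaging$background_phase_sd), side, side
    )
  }
  list(phase = phase, mask = mask, pixel_pitch_um = p)
}

#' Synthesize the phase image of a normal-morphology red blood cell
#'
#' Renders a (possibly elongated) biconcave discocyte: a radially
#' symmetric phase dome with a central dimple, stretched by the shape's
#' elongation, plus additive Gaussian background phase noise drawn from
#' the current RNG stream.
#'
#' @param shape A [cell_shape()] with subtype `normal_like` or
#'   `mildly_deformed`.
#' @param imaging An [imaging_config()].
#' @param theta Cell orientation, radians.
#' @param center_um Sub-pixel centre offset, micrometres (length 2).
#' @param noise Add background phase noise? Set `FALSE` for noiseless
#'   closed-form checks.
#' @return A list with `phase` (matrix, radians), `mask` (logical matrix:
#'   pixels where the noiseless profile exceeds 5% of peak phase) and
#'   `pixel_pitch_um`.
#' @examples
#' img <- make_normal_phase_image(cell_shape("normal_like"), imaging_config())
#' range(img$phase[img$mask])
#' @export
make_normal_phase_image <- function(shape, imaging = imaging_config(),
                                    theta = 0, center_um = c(0, 0),
                                    noise = TRUE) {
  if (!shape$subtype %in% c("normal_like", "mildly_deformed")) {
    abort("`shape$subtype` must be normal_like or mildly_deformed.")
  }
  shape$curvature <- 0
  render_phase_image(shape, imaging, theta, center_um, noise)
}

#' Synthesize the phase image of a critically sickled red blood cell
#'
#' Renders an elongated crescent: the elongated profile of
#' [make_normal_phase_image()] with the centreline bent by `curvature` and
#' no central dimple. With `curvature = 0` it reduces exactly to the
#' elongated biconcave profile at `dimple_depth = 0`.
#'
#' @inheritParams make_normal_phase_image
#' @param shape A [cell_shape()] with subtype `critically_sickled`.
#' @return As [make_normal_phase_image()].
#' @examples
#' sh <- cell_shape("critically_sickled", radius_um = 3, elongation = 2.8,
#'                  curvature = 0.4, peak_phase_rad = 1.6, dimple_depth = 0)
#' img <- make_sickled_phase_image(sh, imaging_config())
#' @export
make_sickled_phase_image <- function(shape, imaging = imaging_config(),
                                     theta = 0, center_um = c(0, 0),
                                     noise = TRUE) {
  if (shape$subtype != "critically_sickled") {
    abort("`shape$subtype` must be critically_sickled.")
  }
  shape$dimple_depth <- 0
  render_phase_image(shape, imaging, theta, center_um, noise)
}

# Draw one cell's shape parameters: truncated-normal marginals coupled by
# a per-cell latent severity factor z through a Gaussian copula with
# per-parameter loading rho (see default_shape_priors()).
draw_shape_params <- function(subtype, priors) {
  pri <- priors[priors$subtype == subtype, , drop = FALSE]
  if (!"rho" %in% names(pri)) pri$rho <- 0
  z <- rnorm(1)
  out <- list()
  # fixed parameter order keeps the RNG stream stable across versions
  for (pn in c("radius_um", "elongation", "curvature",
               "peak_phase_rad", "dimple_depth")) {
    row <- pri[pri$param == pn, , drop = FALSE]
    if (nrow(row) != 1) {
      abort(sprintf("priors must contain one row for %s/%s", subtype, pn))
    }
    x <- row$rho * z + sqrt(1 - row$rho^2) * rnorm(1)
    u <- pnorm(x)
    out[[pn]] <- if (row$sd <= 0) {
      pmin(pmax(row$mean, row$lo), row$hi)
    } else {
      p_lo <- pnorm(row$lo, row$mean, row$sd)
      p_hi <- pnorm(row$hi, row$mean, row$sd)
      qnorm(p_lo + u * (p_hi - p_lo), row$mean, row$sd)
    }
  }
  out
}

#' Generate all cells of one sample
#'
#' Draws each cell's subtype from the population's subtype fractions, its
#' shape parameters from the per-subtype truncated-normal priors, a
#' uniform random orientation and a sub-pixel centre jitter, and renders
#' the phase image. The whole sample is a pure function of the population
#' (including its seed); the caller's RNG state is left untouched.
#'
#' @param pop A [sample_population()].
#' @param imaging An [imaging_config()].
#' @return A tibble with one row per cell: `cell_id`, `sample_id`,
#'   `class`, `subtype` (ground truth), the drawn shape parameters, and
#'   list-columns `phase` and `mask`.
#' @examples
#' cells <- generate_sample(sample_population("NOR", 5, seed = 7))
#' cells$subtype
#' @export
generate_sample <- function(pop, imaging = imaging_config()) {
  stopifnot(inherits(pop, "sample_population"))
  n <- pop$n_cells
  with_seed(pop$seed, {
    subtypes <- sample(cell_subtypes(), n, replace = TRUE,
                       prob = pop$subtype_fractions)
    shapes <- vector("list", n)
    thetas <- numeric(n)
    offs <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      prm <- draw_shape_params(subtypes[i], pop$priors)
      thetas[i] <- runif(1, 0, pi)
      offs[i, ] <- runif(2, -0.5, 0.5) * imaging$pixel_pitch_um
      shapes[[i]] <- cell_shape(
        subtypes[i],
        radius_um = prm$radius_um,
        elongation = max(1, prm$elongation),
        curvature = prm$curvature,
        peak_phase_rad = prm$peak_phase_rad,
        dimple_depth = prm$dimple_depth
      )
    }
    imgs <- vector("list", n)
    for (i in seq_len(n)) {
      sh <- shapes[[i]]
      imgs[[i]] <- if (sh$subtype == "critically_sickled") {
        make_sickled_phase_image(sh, imaging, thetas[i], offs[i, ])
      } else {
        make_normal_phase_image(sh, imaging, thetas[i], offs[i, ])
      }
    }
    tibble(
      cell_id = sprintf("%s_c%06d", pop$sample_id, seq_len(n)),
      sample_id = pop$sample_id,
      class = pop$label,
      subtype = subtypes,
      radius_um = vapply(shapes, `[[`, numeric(1), "radius_um"),
      elongation_true = vapply(shapes, `[[`, numeric(1), "elongation"),
      curvature_true = vapply(shapes, `[[`, numeric(1), "curvature"),
      peak_phase_true = vapply(shapes, `[[`, numeric(1), "peak_phase_rad"),
      dimple_depth_true = vapply(shapes, `[[`, numeric(1), "dimple_depth"),
      theta = thetas,
      phase = imgs |> purrr::map("phase"),
      mask = imgs |> purrr::map("mask")
    )
  })
}

# Phase values are stored in float TIFF as (phase - offset) / scale so
# that the full range, including negative background noise, fits the
# [0,1] range float TIFF writers preserve; both constants are recorded in
# the manifest.
study_phase_scale <- 9
study_phase_offset <- -1

#' Write a synthetic study to disk
#'
#' Generates every sample of a study and writes, per sample, a multi-page
#' 32-bit float TIFF stack (phase in radians, affinely mapped to the
#' unit interval by the recorded `phase_scale` and `phase_offset`) plus a metadata CSV (one row per cell with its ground
#' truth), and a study-level JSON manifest recording seeds, per-sample
#' ground-truth subtype counts and a configuration hash.
#'
#' @param study A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @examples
#' \donttest{
#' st <- default_study(1, cells_per_train = 20, cells_per_test_nor = 10,
#'                     cells_per_test_scd = 10)
#' man <- generate_study(st, tempfile("study"))
#' }
#' @export
generate_study <- function(study, out_dir) {
  stopifnot(inherits(study, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  pops <- study_populations(study)
  samples <- list()
  for (pop in pops) {
    cells <- generate_sample(pop, study$imaging)
    tif <- file.path(out_dir, paste0(pop$sample_id, ".tif"))
    ok <- tryCatch({
      tiff::writeTIFF(
        purrr::map(cells$phase, ~ pmin(pmax(
          (.x - study_phase_offset) / study_phase_scale, 0), 1)),
        tif, bits.per.sample = 32L
      )
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      abort(sprintf("failed to write '%s': %s", tif, conditionMessage(ok)))
    }
    meta <- dplyr::select(cells, -"phase", -"mask")
    meta$page <- seq_len(nrow(meta))
    readr::write_csv(meta, file.path(out_dir,
                                     paste0(pop$sample_id, "_cells.csv")))
    samples[[pop$sample_id]] <- list(
      sample_id = pop$sample_id,
      class = pop$label,
      n_cells = pop$n_cells,
      seed = pop$seed,
      subtype_fractions = as.list(pop$subtype_fractions),
      subtype_counts = as.list(table(factor(cells$subtype,
                                            levels = cell_subtypes()))),
      tiff = basename(tif),
      metadata = paste0(pop$sample_id, "_cells.csv")
    )
  }
  manifest <- list(
    phase_scale = study_phase_scale,
    phase_offset = study_phase_offset,
    imaging = unclass(study$imaging),
    config_hash = rlang::hash(study),
    samples = samples
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a study written by [generate_study()]
#'
#' @param dir Study directory containing `manifest.json`.
#' @param samples Optional character vector restricting which samples to
#'   load.
#' @param segment Re-derive cell masks from the phase images with
#'   [segment_cell()] (default) rather than leaving them absent.
#' @return A tibble of cell records with list-columns `phase` and (if
#'   `segment`) `mask`, in the layout produced by [generate_sample()].
#' @export
read_study <- function(dir, samples = NULL, segment = TRUE) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    abort(sprintf("no manifest.json in '%s'", dir))
  }
  man <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  out <- list()
  for (s in man$samples) {
    if (!is.null(samples) && !s$sample_id %in% samples) next
    meta <- readr::read_csv(file.path(dir, s$metadata),
                            show_col_types = FALSE)
    pages <- tiff::readTIFF(file.path(dir, s$tiff), all = TRUE)
    offset <- man$phase_offset %||% 0
    phase <- purrr::map(pages, ~ .x * man$phase_scale + offset)
    meta$phase <- phase[meta$page]
    if (segment) {
      meta$mask <- purrr::map(meta$phase, segment_cell)
    }
    out[[s$sample_id]] <- meta
  }
  dplyr::bind_rows(out)
}
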