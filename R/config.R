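#' Imaging configuration
#'
#' Describes the reconstructed-phase-image geometry the generator emulates:
#' an off-axis holographic cytometer with a 640 nm source producing
#' single-cell phase maps in radians on a regular pixel grid.
#'
#' @param wavelength_nm Illumination wavelength in nanometres. Used for the
#'   phase-to-optical-path-length conversion.
#' @param pixel_pitch_um Physical size of one pixel in micrometres.
#' @param image_side Side length of the (square) single-cell frame, pixels.
#' @param background_phase_sd Standard deviation of additive Gaussian
#'   background phase noise, radians.
#' @return An object of class `imaging_config`.
#' @examples
#' imaging_config()
#' @export
imaging_config <- function(wavelength_nm = 640,
                           pixel_pitch_um = 0.24,
                           image_side = 64,
                           background_phase_sd = 0.02) {
  stopifnot(wavelength_nm > 0, pixel_pitch_um > 0, background_phase_sd >= 0)
  if (image_side < 32) {
    abort("`image_side` must be at least 32 pixels.")
  }
  structure(
    list(
      wavelength_nm = wavelength_nm,
      pixel_pitch_um = pixel_pitch_um,
      image_side = as.integer(image_side),
      background_phase_sd = background_phase_sd
    ),
    class = "imaging_config"
  )
}

cell_subtypes <- function() {
  c("normal_like", "mildly_deformed", "critically_sickled")
}

#' Parametric description of one cell's shape
#'
#' A smooth parametric stand-in for erythrocyte morphology: a (possibly
#' elongated) biconcave discocyte, or a bent crescent for critically
#' sickled cells.
#'
#' @param subtype One of `"normal_like"`, `"mildly_deformed"`,
#'   `"critically_sickled"`.
#' @param radius_um Discocyte-equivalent radius, micrometres (the elliptical
#'   footprint preserves the area of a disc of this radius).
#' @param elongation Major/minor axis ratio of the generating ellipse
#'   (>= 1).
#' @param curvature Crescent bending of the centreline (0 = straight);
#'   dimensionless, only meaningful for sickled cells.
#' @param peak_phase_rad Peak phase of the cell profile, radians.
#' @param dimple_depth Central biconcave dip as a fraction of peak phase,
#'   in `[0, 1]`.
#' @return An object of class `cell_shape`.
#' @examples
#' cell_shape("normal_like", radius_um = 3.6)
#' @export
cell_shape <- function(subtype,
                       radius_um = 3.6,
                       elongation = 1,
                       curvature = 0,
                       peak_phase_rad = 1.25,
                       dimple_depth = 0.4) {
  subtype <- match.arg(subtype, cell_subtypes())
  stopifnot(
    radius_um > 0, elongation >= 1, curvature >= 0,
    peak_phase_rad > 0, dimple_depth >= 0, dimple_depth <= 1
  )
  structure(
    list(
      subtype = subtype, radius_um = radius_um, elongation = elongation,
      curvature = curvature, peak_phase_rad = peak_phase_rad,
      dimple_depth = dimple_depth
    ),
    class = "cell_shape"
  )
}

#' Default per-subtype shape-parameter distributions
#'
#' Each shape parameter is drawn from a truncated normal. The three
#' subtypes encode the population structure the analysis assumes:
#'
#' * `normal_like` - biconcave discocytes with mild natural ellipticity;
#' * `mildly_deformed` - shape-normal cells with reduced optical density
#'   (lower peak phase), emulating the non-sickled but biophysically
#'   altered majority of cells in a disease sample;
#' * `critically_sickled` - elongated, bent crescents with elevated peak
#'   phase, whose descriptors (eccentricity, elongation, max phase, ...)
#'   extend beyond the support of the normal population.
#'
#' Each parameter additionally carries a loading `rho` on a per-cell
#' latent severity factor (Gaussian copula over the truncated-normal
#' marginals): cells that are more elongated also tend to carry more
#' phase and a shallower dimple, emulating the within-population
#' covariation of deformation and optical density.
#'
#' @return A tibble with columns `subtype`, `param`, `mean`, `sd`, `lo`,
#'   `hi`, `rho`.
#' @examples
#' default_shape_priors()
#' @export
default_shape_priors <- function() {
  row <- function(subtype, param, mean, sd, lo, hi, rho) {
    tibble(subtype = subtype, param = param, mean = mean, sd = sd,
           lo = lo, hi = hi, rho = rho)
  }
  dplyr::bind_rows(
    row("normal_like", "radius_um",      3.60, 0.18, 3.15, 4.05, -0.5),
    row("normal_like", "elongation",     1.15, 0.15, 1.00, 1.80,  0.90),
    row("normal_like", "curvature",      0.00, 0.00, 0.00, 0.00,  0.0),
    row("normal_like", "peak_phase_rad", 1.25, 0.12, 0.90, 1.70,  0.90),
    row("normal_like", "dimple_depth",   0.40, 0.15, 0.00, 0.80, -0.75),

    # shape-near-normal (slightly rounder), optically lighter
    row("mildly_deformed", "radius_um",      3.60, 0.18, 3.15, 4.05, -0.5),
    row("mildly_deformed", "elongation",     1.10, 0.12, 1.00, 1.50,  0.90),
    row("mildly_deformed", "curvature",      0.00, 0.00, 0.00, 0.00,  0.0),
    row("mildly_deformed", "peak_phase_rad", 1.05, 0.09, 0.80, 1.35,  0.90),
    row("mildly_deformed", "dimple_depth",   0.55, 0.12, 0.30, 0.80, -0.75),

    # elongated bent crescents, optically denser
    row("critically_sickled", "radius_um",      3.20, 0.20, 2.70, 3.70,  0.0),
    row("critically_sickled", "elongation",     2.80, 0.30, 2.20, 3.40,  0.7),
    row("critically_sickled", "curvature",      0.40, 0.12, 0.15, 0.70,  0.5),
    row("critically_sickled", "peak_phase_rad", 1.62, 0.15, 1.25, 2.10,  0.7),
    row("critically_sickled", "dimple_depth",   0.00, 0.00, 0.00, 0.00,  0.0)
  )
}

#' Describe one sample's cell population
#'
#' @param label Class label of the donor sample: `"NOR"` or `"SCD"`.
#' @param n_cells Number of cells to generate.
#' @param subtype_fractions Named numeric simplex over the three subtypes
#'   (`normal_like`, `mildly_deformed`, `critically_sickled`). Must sum to
#'   1; normal samples must have zero critically sickled fraction.
#' @param sample_id Identifier used in cell records.
#' @param seed Integer seed making the sample reproducible.
#' @param priors Shape-parameter distributions, see
#'   [default_shape_priors()].
#' @return An object of class `sample_population`.
#' @examples
#' sample_population("SCD", 100, seed = 1)
#' @export
sample_population <- function(label = c("NOR", "SCD"),
                              n_cells,
                              subtype_fractions = NULL,
                              sample_id = NULL,
                              seed = 1L,
                              priors = default_shape_priors()) {
  label <- match.arg(label)
  if (is.null(subtype_fractions)) {
    subtype_fractions <- if (label == "SCD") {
      c(normal_like = 0.25, mildly_deformed = 0.60, critically_sickled = 0.15)
    } else {
      c(normal_like = 0.80, mildly_deformed = 0.20, critically_sickled = 0.00)
    }
  }
  if (!setequal(names(subtype_fractions), cell_subtypes())) {
    abort("`subtype_fractions` must be named with the three cell subtypes.")
  }
  subtype_fractions <- subtype_fractions[cell_subtypes()]
  if (any(subtype_fractions < 0) ||
      abs(sum(subtype_fractions) - 1) > 1e-8) {
    abort("`subtype_fractions` must be a simplex (non-negative, sum 1).")
  }
  if (label == "NOR" && subtype_fractions[["critically_sickled"]] > 0) {
    abort("NOR populations must have zero critically_sickled fraction.")
  }
  if (n_cells < 1) {
    abort("`n_cells` must be at least 1.")
  }
  structure(
    list(
      label = label,
      n_cells = as.integer(n_cells),
      subtype_fractions = subtype_fractions,
      sample_id = sample_id %||% paste0(tolower(label), "_", seed),
      seed = as.integer(seed),
      priors = priors
    ),
    class = "sample_population"
  )
}

#' Multi-sample study configuration
#'
#' A study is the unit the end-to-end pipeline consumes: training samples
#' of both classes plus held-out test samples, mirroring a roster of a few
#' donors with 10^3-10^5 cells each.
#'
#' @param imaging An [imaging_config()].
#' @param train_scd,train_nor Lists of [sample_population()] objects used
#'   for training (at least one of each).
#' @param test_samples List of [sample_population()] objects held out for
#'   sample-level evaluation.
#' @return An object of class `study_config`.
#' @seealso [default_study()]
#' @export
study_config <- function(imaging = imaging_config(),
                         train_scd,
                         train_nor,
                         test_samples = list()) {
  as_pop_list <- function(x) if (inherits(x, "sample_population")) list(x) else x
  train_scd <- as_pop_list(train_scd)
  train_nor <- as_pop_list(train_nor)
  test_samples <- as_pop_list(test_samples)
  if (length(train_scd) < 1 || length(train_nor) < 1) {
    abort("A study needs at least one SCD and one NOR training population.")
  }
  if (!all(vapply(train_scd, function(p) p$label == "SCD", logical(1)))) {
    abort("All `train_scd` populations must be labelled SCD.")
  }
  if (!all(vapply(train_nor, function(p) p$label == "NOR", logical(1)))) {
    abort("All `train_nor` populations must be labelled NOR.")
  }
  structure(
    list(
      imaging = imaging,
      train_scd = train_scd,
      train_nor = train_nor,
      test_samples = test_samples
    ),
    class = "study_config"
  )
}

#' Default synthetic study
#'
#' Two SCD and two NOR training samples (6000 cells each), five NOR test
#' samples (3500 cells each) and one SCD test sample (6000 cells), about
#' 47,500 cells in total -- a desk-scale analogue of a small clinical
#' roster with per-sample counts in the 10^4-10^5 range.
#'
#' @param seed Integer study seed; per-sample seeds are derived from it.
#' @param imaging An [imaging_config()].
#' @param cells_per_train,cells_per_test_nor,cells_per_test_scd Per-sample
#'   cell counts, overridable for smaller runs.
#' @return A `study_config`.
#' @examples
#' st <- default_study(seed = 1, cells_per_train = 50,
#'                     cells_per_test_nor = 20, cells_per_test_scd = 20)
#' @export
default_study <- function(seed = 1L,
                          imaging = imaging_config(),
                          cells_per_train = 6000L,
                          cells_per_test_nor = 3500L,
                          cells_per_test_scd = 6000L) {
  seed <- as.integer(seed)
  base <- (abs(seed) %% 20000L) * 100000L  # room for 100 derived seeds
  pop <- function(label, n, id, k) {
    sample_population(label, n, sample_id = id, seed = base + k)
  }
  study_config(
    imaging = imaging,
    train_scd = list(
      pop("SCD", cells_per_train, "scd_train_1", 1L),
      pop("SCD", cells_per_train, "scd_train_2", 2L)
    ),
    train_nor = list(
      pop("NOR", cells_per_train, "nor_train_4", 4L),
      pop("NOR", cells_per_train, "nor_train_5", 5L)
    ),
    test_samples = list(
      pop("NOR", cells_per_test_nor, "test_nor_A", 11L),
      pop("NOR", cells_per_test_nor, "test_nor_B", 12L),
      pop("NOR", cells_per_test_nor, "test_nor_C", 13L),
      pop("NOR", cells_per_test_nor, "test_nor_D", 14L),
      pop("NOR", cells_per_test_nor, "test_nor_E", 15L),
      pop("SCD", cells_per_test_scd, "test_scd_3", 3L)
    )
  )
}

study_populations <- function(study) {
  c(study$train_scd, study$train_nor, study$test_samples)
}
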