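test_that("noiseless disc profile matches its closed form", {
  img <- make_normal_phase_image(
    cell_shape("normal_like", radius_um = 3, elongation = 1,
               peak_phase_rad = 1.4, dimple_depth = 0),
    imaging_config(image_side = 65), noise = FALSE
  )
  # mask is the disc where the profile exceeds 5% of peak
  v <- (seq_len(65) - 33) * 0.24
  r2 <- outer(v, v, function(y, x) x^2 + y^2) / 9
  expect_identical(img$mask, sqrt(pmax(1 - r2, 0)) > 0.05)
  # peak phase at the centre pixel
  expect_equal(img$phase[33, 33], 1.4, tolerance = 1e-12)
  expect_equal(max(img$phase), 1.4, tolerance = 1e-12)
  expect_true(all(is.finite(img$phase)))
})

test_that("elongation is recovered from mask second moments", {
  for (elong in c(2, 3)) {
    img <- make_sickled_phase_image(
      cell_shape("critically_sickled", radius_um = 2.8, elongation = elong,
                 curvature = 0, peak_phase_rad = 1.5, dimple_depth = 0),
      imaging_config(), noise = FALSE
    )
    f <- compute_features(img$phase, img$mask, 0.24)
    expect_equal(f$elongation_ratio, elong, tolerance = 0.05)
  }
})

test_that("crescent with zero curvature equals the elongated discocyte", {
  sh_s <- cell_shape("critically_sickled", radius_um = 3, elongation = 2.5,
                     curvature = 0, peak_phase_rad = 1.6, dimple_depth = 0)
  sh_n <- cell_shape("mildly_deformed", radius_um = 3, elongation = 2.5,
                     curvature = 0, peak_phase_rad = 1.6, dimple_depth = 0)
  a <- withr::with_seed(1, make_sickled_phase_image(sh_s, imaging_config()))
  b <- withr::with_seed(1, make_normal_phase_image(sh_n, imaging_config()))
  expect_identical(a$phase, b$phase)
  expect_identical(a$mask, b$mask)
})

test_that("generation is deterministic under a fixed seed", {
  pop <- sample_population("SCD", 25, seed = 77)
  a <- generate_sample(pop)
  b <- generate_sample(pop)
  expect_identical(a, b)
})

test_that("cell footprints exceeding the frame raise a geometry error", {
  sh <- cell_shape("normal_like", radius_um = 9, elongation = 1,
                   peak_phase_rad = 1.2, dimple_depth = 0)
  expect_error(
    make_normal_phase_image(sh, imaging_config(), noise = FALSE),
    class = "sicklecyto_geometry_overflow"
  )
})

test_that("subtype draws follow the population fractions", {
  pure <- sample_population(
    "SCD", 100,
    subtype_fractions = c(normal_like = 1, mildly_deformed = 0,
                          critically_sickled = 0),
    seed = 3
  )
  expect_true(all(generate_sample(pure)$subtype == "normal_like"))

  mix <- sample_population(
    "SCD", 10000,
    subtype_fractions = c(normal_like = 0.5, mildly_deformed = 0.35,
                          critically_sickled = 0.15),
    seed = 4
  )
  n_crit <- sum(generate_sample(mix)$subtype == "critically_sickled")
  # binomial bound: within 4 sd of the expected 1500
  expect_lt(abs(n_crit - 1500), 4 * sqrt(10000 * 0.15 * 0.85))
})

test_that("invalid population configurations are rejected", {
  expect_error(
    sample_population("SCD", 10, subtype_fractions =
      c(normal_like = 0.6, mildly_deformed = 0.6, critically_sickled = -0.2)),
    "simplex"
  )
  expect_error(
    sample_population("NOR", 10, subtype_fractions =
      c(normal_like = 0.8, mildly_deformed = 0.1, critically_sickled = 0.1)),
    "critically_sickled"
  )
})

test_that("critically sickled eccentricity sits beyond the normal support", {
  nor <- cell_features(generate_sample(sample_population("NOR", 400, seed = 5)))
  crit <- cell_features(generate_sample(sample_population(
    "SCD", 120,
    subtype_fractions = c(normal_like = 0, mildly_deformed = 0,
                          critically_sickled = 1),
    seed = 6
  )))
  expect_gt(min(crit$eccentricity), max(nor$eccentricity))
})

test_that("mask area scales with the squared radius", {
  areas <- vapply(c(2, 3, 4, 5), function(r) {
    img <- make_normal_phase_image(
      cell_shape("normal_like", radius_um = r, elongation = 1,
                 peak_phase_rad = 1, dimple_depth = 0),
      imaging_config(image_side = 64), noise = FALSE
    )
    sum(img$mask) * 0.24^2
  }, numeric(1))
  ratio <- areas / (pi * c(2, 3, 4, 5)^2)
  expect_true(all(abs(ratio - 1) < 0.1))
})
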