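# Shared fixtures and small oracles, all generated in code.

# Rasterize a filled ellipse mask directly (independent of the image
# generator): semi-axes a, b in pixels, rotation theta, on a square grid.
raster_ellipse <- function(a, b, theta = 0, side = 2 * ceiling(a) + 9) {
  v <- seq_len(side) - (side + 1) / 2
  X <- matrix(v, side, side, byrow = TRUE)
  Y <- matrix(v, side, side)
  xr <- cos(theta) * X + sin(theta) * Y
  yr <- -sin(theta) * X + cos(theta) * Y
  (xr / a)^2 + (yr / b)^2 <= 1
}

raster_disc <- function(r, side = 2 * ceiling(r) + 9) {
  raster_ellipse(r, r, 0, side)
}

# Brute-force tail search oracle: evaluates the smoothed population-ratio
# at every candidate threshold by explicit counting, and returns the
# qualifying threshold with maximal tail count.
oracle_tail_search <- function(s, n, direction, ratio = 21, pseudo = 1) {
  cand <- sort(unique(c(s, n)))
  best <- NULL
  for (t in cand) {
    if (direction == "lower") {
      ns <- sum(s <= t); nn <- sum(n <= t)
    } else {
      ns <- sum(s >= t); nn <- sum(n >= t)
    }
    r <- (ns / length(s)) / ((nn + pseudo) / (length(n) + pseudo))
    if (ns >= 1 && r >= ratio) {
      if (is.null(best) || ns > best$n_scd_tail) {
        best <- list(threshold = t, achieved_ratio = r,
                     n_scd_tail = ns, n_nor_tail = nn)
      }
    }
  }
  best
}

# Pairwise-concordance AUC oracle (ties count one half).
oracle_auc <- function(scores, labels, positive = "SCD") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# Memoised study data shared across test files. For each seed, generates
# the four training samples plus one normal and one disease test sample
# of the default study, extracts features, applies QC, and optionally
# keeps CNN input rows for the same cells.
.study_cache <- new.env(parent = emptyenv())

study_data <- function(seed, with_crops = FALSE) {
  key_crops <- paste0("seed", seed, "_crops")
  key <- if (with_crops) key_crops else paste0("seed", seed)
  if (!is.null(.study_cache[[key_crops]])) {
    return(.study_cache[[key_crops]])
  }
  if (!is.null(.study_cache[[key]])) {
    return(.study_cache[[key]])
  }
  st <- default_study(seed = seed)
  pops <- c(st$train_scd, st$train_nor,
            Filter(function(p) p$sample_id %in% c("test_nor_A", "test_scd_3"),
                   st$test_samples))
  crop_cfg <- train_config("cnn")
  feats <- list()
  crops <- list()
  for (pop in pops) {
    cells <- generate_sample(pop, st$imaging)
    f <- cell_features(cells, st$imaging$pixel_pitch_um,
                       st$imaging$wavelength_nm, keep_images = with_crops)
    if (with_crops) {
      crops[[pop$sample_id]] <- prepare_cnn_inputs(f, crop_cfg)
      f <- dplyr::select(f, -phase, -mask)
    }
    feats[[pop$sample_id]] <- f
    rm(cells)
  }
  feats <- dplyr::bind_rows(feats)
  feats <- qc_filter(feats)
  X <- if (with_crops) do.call(rbind, crops) else NULL
  if (with_crops) X <- X[feats$qc_pass, , drop = FALSE]
  kept <- dplyr::filter(feats, qc_pass)
  train_ids <- c("scd_train_1", "scd_train_2", "nor_train_4", "nor_train_5")
  out <- list(
    all = feats,
    train = dplyr::filter(kept, sample_id %in% train_ids),
    test = dplyr::filter(kept, !sample_id %in% train_ids),
    crops = X,
    crop_rows = if (with_crops) kept$cell_id else NULL
  )
  .study_cache[[key]] <- out
  out
}

# Refinement of a cached study's training table under default config.
refine_study <- function(sd) {
  criteria <- search_all_parameters(sd$train)
  refined <- suppressWarnings(build_refined_set(sd$train, criteria))
  list(criteria = criteria, refined = refined)
}
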