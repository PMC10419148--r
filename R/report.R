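#' Sample-level decision thresholds
#'
#' The decision model calls a sample diseased when the predicted
#' percentage of critically sickled cells exceeds the lower bound
#' (strictly, "more than 8%"); the 8-25% range is additionally reported
#' as a severity band position.
#'
#' @param lower_bound_pct Lower bound, percent (call threshold).
#' @param upper_band_pct Upper bound of the severity band, percent.
#' @return An object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(lower_bound_pct = 8, upper_band_pct = 25) {
  if (!(lower_bound_pct > 0 && lower_bound_pct < upper_band_pct &&
        upper_band_pct < 100)) {
    abort("need 0 < lower_bound_pct < upper_band_pct < 100")
  }
  structure(
    list(lower_bound_pct = lower_bound_pct,
         upper_band_pct = upper_band_pct),
    class = "decision_thresholds"
  )
}

#' Sample-level disease call from a predicted percentage
#'
#' @param pct_scd Predicted percentage of disease-class cells in the
#'   sample, in `[0, 100]` (vectorised).
#' @param thresholds A [decision_thresholds()].
#' @return Character vector: `"SCD"` where `pct_scd` strictly exceeds the
#'   lower bound, else `"NORMAL"`.
#' @examples
#' decide_sample(c(7.38, 8, 25.96))
#' @export
decide_sample <- function(pct_scd, thresholds = decision_thresholds()) {
  if (any(!is.finite(pct_scd)) || any(pct_scd < 0) || any(pct_scd > 100)) {
    abort("`pct_scd` must be within [0, 100]")
  }
  ifelse(pct_scd > thresholds$lower_bound_pct, "SCD", "NORMAL")
}

severity_band_position <- function(pct_scd, thresholds) {
  pos <- (pct_scd - thresholds$lower_bound_pct) /
    (thresholds$upper_band_pct - thresholds$lower_bound_pct)
  pmax(pos, 0)
}

#' Per-sample prediction report
#'
#' Scores every cell with a trained classifier, tabulates the predicted
#' percentage of normal and disease cells per sample and applies the
#' sample-level decision model.
#'
#' @param fit An `scd_fit` from [train_logistic()] or [train_cnn()].
#' @param data Cell table (features for LR, phase crops for CNN) with a
#'   sample identifier column.
#' @param thresholds A [decision_thresholds()].
#' @param sample_col Name of the sample identifier column.
#' @return A tibble with one row per sample: `sample_id`, `pct_normal`,
#'   `pct_scd`, `n_cells`, `call` and `severity_band_position`
#'   (`(pct_scd - lower) / (upper - lower)`, clipped below at 0; values
#'   above 1 indicate disease burden beyond the band).
#' @export
evaluate_samples <- function(fit, data,
                             thresholds = decision_thresholds(),
                             sample_col = "sample_id") {
  if (!sample_col %in% names(data)) {
    abort(sprintf("data has no '%s' column", sample_col))
  }
  if (nrow(data) == 0) {
    abort("cannot evaluate an empty sample table")
  }
  model <- if (inherits(fit, "scd_fit")) fit$model else fit
  preds <- predict_cells(fit, data)
  out <- tibble(sample_id = data[[sample_col]],
                is_pos = preds$label == model$positive) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      pct_normal = 100 * mean(!.data$is_pos),
      pct_scd = 100 * mean(.data$is_pos),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
  out$call <- decide_sample(out$pct_scd, thresholds)
  out$severity_band_position <-
    severity_band_position(out$pct_scd, thresholds)
  class(out) <- c("sample_report", class(out))
  out
}

#' Run the full analysis chain on a synthetic study
#'
#' Executes simulate -> features -> QC -> selective-search refinement ->
#' train (refined and unrefined variants) -> per-sample evaluation ->
#' sample-level decision, streaming sample by sample so full-resolution
#' images of only one sample are held in memory at a time.
#'
#' @param study A [study_config()], e.g. [default_study()].
#' @param refine_cfg A [refine_config()].
#' @param lr_cfg A [train_config()] for the logistic models.
#' @param cnn_cfg A [train_config()] for the CNN models, or `NULL` to
#'   skip the CNN variants.
#' @param thresholds A [decision_thresholds()].
#' @param max_train_per_class Cap on per-class cell count for the
#'   unrefined (ALL) training variant.
#' @param out_dir Optional directory; when given, feature tables,
#'   criteria, refined-set membership and the summary are written as
#'   CSV/JSON.
#' @return A list of class `hc_pipeline`: `features` (QC-annotated
#'   feature table), `qc` (QC tally), `criteria`, `refined`, `fits`
#'   (named `lr_all`, `lr_sel`, and with `cnn_cfg` also `cnn_all`,
#'   `cnn_sel`), `reports` (per-variant sample reports), `summary` (long
#'   table across variants) and `conservation` (cell accounting).
#' @export
run_pipeline <- function(study = default_study(),
                         refine_cfg = refine_config(),
                         lr_cfg = train_config("lr"),
                         cnn_cfg = NULL,
                         thresholds = decision_thresholds(),
                         max_train_per_class = 10000L,
                         out_dir = NULL) {
  stopifnot(inherits(study, "study_config"))
  keep_crops <- !is.null(cnn_cfg)
  crop_cfg <- cnn_cfg %||% train_config("cnn")

  pops <- study_populations(study)
  train_ids <- vapply(c(study$train_scd, study$train_nor),
                      function(p) p$sample_id, character(1))
  feats <- list()
  crops <- list()
  for (pop in pops) {
    cells <- generate_sample(pop, study$imaging)
    f <- cell_features(cells, study$imaging$pixel_pitch_um,
                       study$imaging$wavelength_nm, keep_images = TRUE)
    if (keep_crops) {
      f$crop <- purrr::map(f$phase, function(img) {
        EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                           w = crop_cfg$input_side,
                                           h = crop_cfg$input_side))
      })
    }
    feats[[pop$sample_id]] <- dplyr::select(f, -"phase", -"mask")
    rm(cells, f)
  }
  features <- dplyr::bind_rows(feats)
  rm(feats)

  n_sim <- nrow(features)
  features <- qc_filter(features, class_col = "class")
  kept <- dplyr::filter(features, .data$qc_pass)
  conservation <- list(
    cells_simulated = n_sim,
    cells_kept = nrow(kept),
    cells_qc_excluded = sum(!features$qc_pass),
    cells_unsegmentable = 0L
  )

  is_train <- kept$sample_id %in% train_ids
  train_tbl <- kept[is_train, , drop = FALSE]
  test_tbl <- kept[!is_train, , drop = FALSE]

  criteria <- search_all_parameters(train_tbl, refine_cfg)
  refined <- build_refined_set(train_tbl, criteria, refine_cfg)
  sel_tbl <- refined_training_table(train_tbl, refined)

  all_tbl <- with_seed(refine_cfg$seed, {
    dplyr::bind_rows(lapply(c("SCD", "NOR"), function(cl) {
      sub <- train_tbl[train_tbl$class == cl, , drop = FALSE]
      if (nrow(sub) > max_train_per_class) {
        sub <- sub[sample.int(nrow(sub), max_train_per_class), , drop = FALSE]
      }
      sub
    }))
  })

  fits <- list()
  lr_all_cfg <- modifyList(lr_cfg, list(variant = "ALL"))
  lr_sel_cfg <- modifyList(lr_cfg, list(variant = "SEL"))
  class(lr_all_cfg) <- class(lr_sel_cfg) <- "train_config"
  fits$lr_all <- train_logistic(all_tbl, lr_all_cfg)
  fits$lr_sel <- train_logistic(sel_tbl, lr_sel_cfg)
  if (!is.null(cnn_cfg)) {
    cnn_all_cfg <- modifyList(cnn_cfg, list(variant = "ALL"))
    cnn_sel_cfg <- modifyList(cnn_cfg, list(variant = "SEL"))
    class(cnn_all_cfg) <- class(cnn_sel_cfg) <- "train_config"
    fits$cnn_all <- train_cnn(all_tbl, cnn_all_cfg)
    fits$cnn_sel <- train_cnn(sel_tbl, cnn_sel_cfg)
  }

  reports <- purrr::map(fits, evaluate_samples, data = test_tbl,
                        thresholds = thresholds)
  summary <- dplyr::bind_rows(purrr::imap(reports, function(rep, nm) {
    dplyr::mutate(rep, variant = nm, .before = 1)
  }))
  truth <- dplyr::distinct(test_tbl, .data$sample_id, .data$class)
  summary <- dplyr::left_join(summary, truth, by = "sample_id")

  out <- structure(
    list(features = features, qc = qc_summary(features),
         criteria = criteria, refined = refined, fits = fits,
         reports = reports, summary = summary,
         conservation = conservation,
         thresholds = thresholds),
    class = "hc_pipeline"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    feat_out <- features
    if ("crop" %in% names(feat_out)) feat_out$crop <- NULL
    readr::write_csv(feat_out, file.path(out_dir, "features.csv"))
    readr::write_csv(criteria, file.path(out_dir, "criteria.csv"))
    readr::write_csv(tidy(refined), file.path(out_dir, "refined_set.csv"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    jsonlite::write_json(
      list(conservation = conservation,
           qc = qc_summary(features),
           criteria = criteria,
           metrics = purrr::map(fits, ~ glance(.x))),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' @export
print.hc_pipeline <- function(x, ...) {
  cat("<hc_pipeline>\n")
  cat(sprintf("  cells: %d simulated, %d kept, %d QC-excluded\n",
              x$conservation$cells_simulated, x$conservation$cells_kept,
              x$conservation$cells_qc_excluded))
  cat(sprintf("  criteria: %d; refined set: %d + %d\n",
              nrow(x$criteria), length(x$refined$scd_ids),
              length(x$refined$nor_ids)))
  cat(sprintf("  variants: %s\n", paste(names(x$fits), collapse = ", ")))
  invisible(x)
}
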