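#' Prepare phase crops as CNN input rows
#'
#' Resamples each cell's phase image to a fixed square side (bilinear) and
#' scales phase to `[0, 1]` by a fixed global cap, clamping values beyond
#' it. Masking is deliberately not applied: the network sees the raw crop.
#'
#' @param cells Cell table with a `phase` list-column (or a previously
#'   prepared `crop` list-column, used as-is).
#' @param config A [train_config()] supplying `input_side` and
#'   `phase_cap`.
#' @return A numeric matrix with one row per cell (`input_side^2`
#'   columns, column-major pixel order).
#' @export
prepare_cnn_inputs <- function(cells, config = train_config("cnn")) {
  side <- config$input_side
  src <- if ("crop" %in% names(cells)) cells$crop else cells$phase
  if (is.null(src)) {
    abort("cell table needs a `phase` (or `crop`) list-column")
  }
  rows <- purrr::map(src, function(img) {
    if (is.null(dim(img)) || any(!is.finite(img))) {
      abort("invalid phase image for CNN input")
    }
    if (!all(dim(img) == c(side, side))) {
      img <- EBImage::imageData(
        EBImage::resize(EBImage::Image(img), w = side, h = side)
      )
    }
    as.numeric(pmin(pmax(img / config$phase_cap, 0), 1))
  })
  do.call(rbind, rows)
}

cnn_init_weights <- function(config) {
  ch <- config$channels
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  list(
    W1 = he(ch[1], 9, 9), b1 = rep(0, ch[1]),
    W2 = he(ch[2], ch[1] * 9, ch[1] * 9), b2 = rep(0, ch[2]),
    W3 = he(ch[3], ch[2] * 9, ch[2] * 9), b3 = rep(0, ch[3]),
    w4 = rnorm(ch[3], 0, sqrt(1 / ch[3])), b4 = 0
  )
}

cnn_fit_core <- function(X, y01, config) {
  n <- nrow(X)
  perm <- t(replicate(config$epochs, sample.int(n) - 1L))
  if (config$epochs == 1) perm <- matrix(perm, nrow = 1)
  w0 <- cnn_init_weights(config)
  cnn_train_cpp(X, y01, config$input_side, w0, config$epochs,
                config$batch_size, config$learning_rate, perm)
}

#' Train the convolutional classifier on phase crops
#'
#' Same split/repeat/metric protocol as [train_logistic()], but the model
#' is a compact convolutional network operating on resampled phase crops:
#' three 3x3-conv/ReLU/2x2-max-pool blocks, global average pooling and a
#' single sigmoid output, optimised with Adam on binary cross-entropy.
#' Weight initialisation and batch shuffling are driven by the configured
#' seed, so a fixed configuration trains to identical weights.
#'
#' @param cells Cell table with a `phase` (or `crop`) list-column and the
#'   label column.
#' @param config A [train_config()] with `model = "cnn"`.
#' @param label_col,positive,negative Label column and class labels.
#' @return An `scd_fit` (see [train_logistic()]).
#' @export
train_cnn <- function(cells, config = train_config("cnn"),
                      label_col = "class",
                      positive = "SCD", negative = "NOR") {
  labels <- cells[[label_col]]
  check_two_classes(labels, positive, negative)
  X <- prepare_cnn_inputs(cells, config)
  y01 <- as.numeric(labels == positive)

  per_repeat <- list()
  val_scores <- c()
  val_labels <- c()
  n_train <- n_val <- 0L
  for (r in seq_len(config$repeats)) {
    with_seed(config$seed + r - 1L, {
      tr <- stratified_split(labels, config$train_fraction)
      w <- cnn_fit_core(X[tr, , drop = FALSE], y01[tr], config)
      sc <- as.numeric(cnn_predict_cpp(w, X[!tr, , drop = FALSE],
                                       config$input_side, 256L))
      per_repeat[[r]] <- confusion_metrics(labels[!tr], sc > 0.5, positive)
      val_scores <- c(val_scores, sc)
      val_labels <- c(val_labels, labels[!tr])
      n_train <- sum(tr)
      n_val <- sum(!tr)
    })
  }
  ra <- roc_auc(val_scores, val_labels, positive)
  metrics <- new_metrics_report(dplyr::bind_rows(per_repeat),
                                ra$roc, ra$auc, n_train, n_val)
  w_final <- with_seed(config$seed, cnn_fit_core(X, y01, config))
  model <- structure(
    list(kind = "cnn", weights = w_final[c("W1", "b1", "W2", "b2",
                                           "W3", "b3", "w4", "b4")],
         epoch_loss = w_final$epoch_loss,
         input_side = config$input_side, phase_cap = config$phase_cap,
         positive = positive, negative = negative, config = config,
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(config),
                           n = nrow(cells))),
    class = "scd_cnn"
  )
  structure(list(model = model, metrics = metrics), class = "scd_fit")
}

#' @export
predict.scd_cnn <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) {
    newdata
  } else {
    prepare_cnn_inputs(newdata, object$config)
  }
  if (ncol(X) != object$input_side^2) {
    abort(sprintf("CNN expects %d-pixel inputs, got %d",
                  object$input_side^2, ncol(X)))
  }
  as.numeric(cnn_predict_cpp(object$weights, X, object$input_side, 256L))
}
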