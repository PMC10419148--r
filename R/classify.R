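#' Training protocol configuration
#'
#' Shared protocol for both classifier families: `repeats` stratified
#' 90/10 train/validation splits, metrics averaged over repeats, final
#' model refit on all data.
#'
#' @param model `"lr"` (logistic regression on the 25 features) or
#'   `"cnn"` (convolutional network on phase crops).
#' @param variant `"ALL"` (unrefined donor labels) or `"SEL"` (refined
#'   set); informational tag recorded in provenance.
#' @param train_fraction Fraction of data used for training each repeat.
#' @param repeats Number of split/fit repeats.
#' @param seed Base seed; repeat `i` uses `seed + i - 1`.
#' @param l2 Ridge penalty for the logistic regression (the refined
#'   classes are nearly separable, so an unregularized fit diverges).
#' @param input_side CNN input side after resampling, pixels.
#' @param phase_cap Fixed global phase cap (radians) scaling CNN inputs to
#'   `[0, 1]`.
#' @param channels CNN channel widths of the three conv blocks.
#' @param epochs,batch_size,learning_rate CNN optimisation settings.
#' @return An object of class `train_config`.
#' @export
train_config <- function(model = c("lr", "cnn"),
                         variant = c("ALL", "SEL"),
                         train_fraction = 0.9,
                         repeats = 5L,
                         seed = 1L,
                         l2 = 1e-3,
                         input_side = 32L,
                         phase_cap = 3,
                         channels = c(16L, 32L, 64L),
                         epochs = 5L,
                         batch_size = 64L,
                         learning_rate = 3e-3) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  stopifnot(train_fraction > 0, train_fraction < 1, repeats >= 1,
            l2 >= 0, input_side >= 8, phase_cap > 0,
            length(channels) == 3, epochs >= 1)
  structure(
    list(model = model, variant = variant,
         train_fraction = train_fraction, repeats = as.integer(repeats),
         seed = as.integer(seed), l2 = l2,
         input_side = as.integer(input_side), phase_cap = phase_cap,
         channels = as.integer(channels), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate),
    class = "train_config"
  )
}

check_two_classes <- function(labels, positive, negative) {
  if (!positive %in% labels || !negative %in% labels) {
    abort("training data must contain both classes")
  }
  if (!all(labels %in% c(positive, negative))) {
    abort("training labels outside the two expected classes")
  }
}

feature_matrix <- function(features, feature_cols) {
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  bad <- !is.finite(X)
  if (any(bad)) {
    row <- which(rowSums(bad) > 0)[1]
    id <- if ("cell_id" %in% names(features)) features$cell_id[row] else row
    abort(sprintf("non-finite feature value for cell %s", id))
  }
  X
}

fit_lr_core <- function(X, y01, l2) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd_pop)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  fit <- glmnet::glmnet(Xs, y01, family = "binomial", alpha = 0,
                        lambda = l2, standardize = FALSE)
  list(beta = as.numeric(fit$beta), intercept = as.numeric(fit$a0),
       center = center, scale = scale)
}

lr_scores <- function(core, X) {
  Xs <- sweep(sweep(X, 2, core$center), 2, core$scale, "/")
  eta <- as.numeric(Xs %*% core$beta) + core$intercept
  1 / (1 + exp(-eta))
}

#' Train a logistic-regression classifier on morphological features
#'
#' Fits ridge-regularized logistic regression (disease class positive) on
#' internally standardized features. For each repeat a stratified
#' 90/10 split is drawn, the model fit on the training part and
#' sensitivity/specificity/accuracy measured on the validation part; the
#' ROC/AUC is computed from the pooled validation scores. The returned
#' model is refit on all data.
#'
#' @param features Feature table with the label column and feature
#'   columns.
#' @param config A [train_config()] with `model = "lr"`.
#' @param feature_cols Feature columns used (default the 25 parameters).
#' @param label_col,positive,negative Label column and class labels.
#' @return An object of class `scd_fit` with elements `model` and
#'   `metrics` (a `metrics_report`).
#' @examples
#' \donttest{
#' cells <- dplyr::bind_rows(
#'   generate_sample(sample_population("SCD", 150, seed = 1)),
#'   generate_sample(sample_population("NOR", 150, seed = 2)))
#' feats <- cell_features(cells)
#' fit <- train_logistic(feats, train_config("lr", repeats = 2))
#' glance(fit)
#' }
#' @export
train_logistic <- function(features, config = train_config("lr"),
                           feature_cols = feature_names(),
                           label_col = "class",
                           positive = "SCD", negative = "NOR") {
  labels <- features[[label_col]]
  check_two_classes(labels, positive, negative)
  X <- feature_matrix(features, feature_cols)
  y01 <- as.integer(labels == positive)

  per_repeat <- list()
  val_scores <- c()
  val_labels <- c()
  n_train <- n_val <- 0L
  for (r in seq_len(config$repeats)) {
    with_seed(config$seed + r - 1L, {
      tr <- stratified_split(labels, config$train_fraction)
      core <- fit_lr_core(X[tr, , drop = FALSE], y01[tr], config$l2)
      sc <- lr_scores(core, X[!tr, , drop = FALSE])
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
  core <- with_seed(config$seed, fit_lr_core(X, y01, config$l2))
  model <- structure(
    list(kind = "lr", core = core, feature_cols = feature_cols,
         positive = positive, negative = negative, config = config,
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(config),
                           n = nrow(features))),
    class = "scd_lr"
  )
  structure(list(model = model, metrics = metrics), class = "scd_fit")
}

#' @export
print.scd_fit <- function(x, ...) {
  cat(sprintf("<scd_fit> %s (%s variant), trained on n=%d\n",
              toupper(x$model$kind), x$model$config$variant,
              x$model$provenance$n))
  print(x$metrics)
  invisible(x)
}

#' @export
predict.scd_lr <- function(object, newdata, ...) {
  X <- feature_matrix(newdata, object$feature_cols)
  lr_scores(object$core, X)
}

#' @describeIn train_logistic Coefficients of the fitted logistic
#'   regression (on standardized features).
#' @param x An `scd_fit`.
#' @param ... Unused.
#' @export
tidy.scd_fit <- function(x, ...) {
  if (x$model$kind == "lr") {
    tibble(
      term = c("(Intercept)", x$model$feature_cols),
      estimate = c(x$model$core$intercept, x$model$core$beta)
    )
  } else {
    w <- x$model$weights
    tibble(
      term = names(w),
      n_parameters = vapply(w, length, integer(1))
    )
  }
}

#' @describeIn train_logistic One-row metric summary of a fit.
#' @export
glance.scd_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(model = x$model$kind, variant = x$model$config$variant),
    glance(x$metrics)
  )
}

#' Score cells with a trained classifier
#'
#' @param fit An `scd_fit` (or bare model) from [train_logistic()] or
#'   [train_cnn()].
#' @param data Feature table (LR) or cell table with phase crops /
#'   list-columns (CNN).
#' @return A tibble with `cell_id` (if present in `data`), `score` in
#'   `[0, 1]` and `label` (`positive` when `score > 0.5`, strictly;
#'   a score of exactly 0.5 is called normal).
#' @export
predict_cells <- function(fit, data) {
  model <- if (inherits(fit, "scd_fit")) fit$model else fit
  score <- predict(model, data)
  out <- tibble(
    score = score,
    label = ifelse(score > 0.5, model$positive, model$negative)
  )
  if ("cell_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble(cell_id = data$cell_id), out)
  }
  out
}
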