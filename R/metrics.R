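#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all distinct score values as thresholds (tied scores move as a
#' block), yielding the ROC polyline from (0,0) to (1,1); the AUC is the
#' trapezoidal area under it, which equals the pairwise concordance
#' probability with ties counted one half.
#'
#' @param scores Numeric classifier scores (higher = more disease-like).
#' @param labels Class labels aligned with `scores`.
#' @param positive Label of the positive (disease) class.
#' @return A list with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.2), c("SCD", "SCD", "NOR", "NOR"))$auc
#' @export
roc_auc <- function(scores, labels, positive = "SCD") {
  y <- labels == positive
  if (!any(y) || all(y)) {
    abort("ROC needs both classes present")
  }
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  P <- sum(y)
  N <- sum(!y)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # collapse tied scores: cumulative counts at each distinct value
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(yy)[last_of_tie]
  fp <- cumsum(!yy)[last_of_tie]
  roc <- tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / N),
    tpr = c(0, tp / P)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

confusion_metrics <- function(truth, predicted, positive = "SCD") {
  pos <- truth == positive
  tp <- sum(pos & predicted)
  fn <- sum(pos & !predicted)
  tn <- sum(!pos & !predicted)
  fp <- sum(!pos & predicted)
  tibble(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp)
  )
}

# Stratified train/validation split: within each class, a random
# train_fraction goes to training.
stratified_split <- function(labels, train_fraction) {
  idx_train <- logical(length(labels))
  for (cl in unique(labels)) {
    ii <- which(labels == cl)
    n_tr <- max(1, round(length(ii) * train_fraction))
    n_tr <- min(n_tr, length(ii) - 1)  # keep at least one validation cell
    idx_train[sample(ii, n_tr)] <- TRUE
  }
  idx_train
}

new_metrics_report <- function(per_repeat, roc, auc, n_train, n_val) {
  structure(
    list(
      summary = tidyr::pivot_longer(
        per_repeat, dplyr::all_of(c("sensitivity", "specificity", "accuracy")),
        names_to = "metric", values_to = "value"
      ) |>
        dplyr::group_by(.data$metric) |>
        dplyr::summarise(mean = mean(.data$value),
                         sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
                         .groups = "drop"),
      per_repeat = per_repeat,
      roc = roc,
      auc = auc,
      n_train = n_train,
      n_val = n_val
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d repeat(s), n_train=%d, n_val=%d, AUC=%.4f\n",
              nrow(x$per_repeat), x$n_train, x$n_val, x$auc))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.2f %% +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @export
glance.metrics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(wide, tibble(auc = x$auc, n_train = x$n_train,
                                n_val = x$n_val))
}
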