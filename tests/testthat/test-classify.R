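gauss_features <- function(n_per_class, delta, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    k <- length(feature_names())
    X <- rbind(
      matrix(rnorm(n_per_class * k, delta, sd), n_per_class, k),
      matrix(rnorm(n_per_class * k, -delta, sd), n_per_class, k)
    )
    colnames(X) <- feature_names()
    dplyr::bind_cols(
      tibble::tibble(
        cell_id = sprintf("c%05d", seq_len(2 * n_per_class)),
        class = rep(c("SCD", "NOR"), each = n_per_class)
      ),
      tibble::as_tibble(X)
    )
  })
}

test_that("well-separated classes train to near-perfect accuracy", {
  tb <- gauss_features(1000, delta = 5, sd = 0.1)
  fit <- train_logistic(tb, train_config("lr", repeats = 3, seed = 9))
  g <- glance(fit)
  expect_gte(g$mean_accuracy, 99)
  expect_gte(g$auc, 0.999)
})

test_that("permuted labels train to chance accuracy", {
  tb <- gauss_features(1000, delta = 5, sd = 0.1)
  tb$class <- withr::with_seed(4, sample(tb$class))
  fit <- train_logistic(tb, train_config("lr", repeats = 5, seed = 9))
  expect_lt(abs(glance(fit)$mean_accuracy - 50), 3)
})

test_that("training is deterministic for a fixed configuration", {
  tb <- gauss_features(200, delta = 1)
  cfg <- train_config("lr", repeats = 2, seed = 5)
  a <- train_logistic(tb, cfg)
  b <- train_logistic(tb, cfg)
  expect_identical(a$metrics$per_repeat, b$metrics$per_repeat)
  expect_identical(a$model$core, b$model$core)
  expect_identical(predict_cells(a, tb), predict_cells(b, tb))
})

test_that("degenerate training inputs raise informative errors", {
  tb <- gauss_features(50, delta = 1)
  expect_error(train_logistic(dplyr::filter(tb, class == "SCD")),
               "both classes")
  tb$mean_phase[3] <- Inf
  expect_error(train_logistic(tb), tb$cell_id[3])
})

test_that("a score of exactly one half is called normal", {
  model <- structure(
    list(kind = "lr",
         core = list(beta = rep(0, 25), intercept = 0,
                     center = rep(0, 25), scale = rep(1, 25)),
         feature_cols = feature_names(),
         positive = "SCD", negative = "NOR",
         config = train_config("lr")),
    class = "scd_lr"
  )
  tb <- gauss_features(3, delta = 1)
  pred <- predict_cells(model, tb)
  expect_true(all(pred$score == 0.5))
  expect_true(all(pred$label == "NOR"))
})

test_that("accuracy is the prevalence-weighted mean of sensitivity and specificity", {
  tb <- gauss_features(300, delta = 0.3, sd = 1, seed = 3)
  cfg <- train_config("lr", repeats = 4, seed = 2)
  fit <- train_logistic(tb, cfg)
  pr <- fit$metrics$per_repeat
  n_val <- fit$metrics$n_val
  p <- n_val / 2  # stratified equal classes
  expect_equal(pr$accuracy, (pr$sensitivity * p + pr$specificity * p) / n_val)
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  truth <- rep(c("SCD", "NOR"), c(60, 40))
  predicted_scd <- c(rep(TRUE, 45), rep(FALSE, 15), rep(TRUE, 10),
                     rep(FALSE, 30))
  m1 <- sicklecyto:::confusion_metrics(truth, predicted_scd, "SCD")
  m2 <- sicklecyto:::confusion_metrics(truth, !predicted_scd, "NOR")
  expect_equal(m1$sensitivity, m2$specificity)
  expect_equal(m1$specificity, m2$sensitivity)
})

test_that("ROC sweep reproduces hand-computed curves", {
  ra <- roc_auc(c(1, 1, 0, 0), c("SCD", "SCD", "NOR", "NOR"))
  expect_equal(ra$auc, 1.0)
  ra2 <- roc_auc(c(0.9, 0.4, 0.6, 0.2), c("SCD", "SCD", "NOR", "NOR"))
  expect_equal(ra2$auc, 0.75)  # 3 of 4 concordant pairs
  ra3 <- roc_auc(rep(0.7, 10), rep(c("SCD", "NOR"), 5))
  expect_equal(ra3$auc, 0.5)
  expect_error(roc_auc(1:3, rep("SCD", 3)), "both classes")
  # curve is monotone from (0,0) to (1,1)
  expect_true(all(diff(ra2$roc$fpr) >= 0))
  expect_true(all(diff(ra2$roc$tpr) >= 0))
  expect_equal(ra2$roc$fpr[1], 0)
  expect_equal(dplyr::last(ra2$roc$tpr), 1)
})

test_that("trapezoidal AUC equals pairwise concordance with ties", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, TRUE)
    labels <- sample(c("SCD", "NOR"), n, TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("SCD", "NOR")
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  scores <- runif(200)
  labels <- ifelse(runif(200) < plogis(4 * scores - 2), "SCD", "NOR")
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    labels, scores, levels = c("NOR", "SCD"), direction = "<", quiet = TRUE
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})
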