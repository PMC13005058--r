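test_that("folds are participant-stratified, leak-free and balanced", {
  ids <- sprintf("P%02d", 1:21)
  labels <- rep(c(0, 1), c(14, 7))
  folds <- make_folds(ids, labels, k = 7, seed = 1)
  expect_length(folds, 7)
  for (f in folds) {
    expect_length(f$test, 3)
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), ids)
    # 14 class-0 + 7 class-1 at k = 7: every test set is exactly 2 + 1
    expect_equal(sum(labels[match(f$test, ids)] == 0), 2)
    expect_equal(sum(labels[match(f$test, ids)] == 1), 1)
  }
  # test sets partition the cohort
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0)

  expect_error(make_folds(ids, rep(0, 21), k = 7), "both classes")
  expect_error(make_folds(ids[c(1:3, 15:16)], labels[c(1:3, 15:16)], k = 7), "fewer participants")
})

test_that("class weights follow the inverse-frequency formula", {
  expect_equal(unname(class_weights(rep(0:1, each = 25))), c(1, 1))
  w <- class_weights(rep(c(0, 1), c(30, 10)))
  expect_equal(unname(w), c(40 / 60, 40 / 20), tolerance = 1e-12)
  expect_equal(
    unname(class_weights(sample(rep(c(0, 1), c(30, 10))))), unname(w)
  )
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("the scaler standardizes with training statistics only", {
  set.seed(6)
  tr <- toy_tensor(n = 20, C = 3, L = 15)
  sc <- fit_scaler(tr)
  z <- apply_scaler(sc, tr)
  for (c in 1:3) {
    expect_lt(abs(mean(z$data[, c, ])), 1e-9)
    expect_equal(stats::sd(as.vector(z$data[, c, ])), 1, tolerance = 1e-9)
  }

  # a shifted test tensor transformed with training statistics differs from
  # its own z-score
  te <- toy_tensor(n = 10, C = 3, L = 15, seed = 9)
  te$data <- te$data + 3
  z_tr_stats <- apply_scaler(sc, te)
  z_own <- apply_scaler(fit_scaler(te), te)
  expect_gt(abs(mean(z_tr_stats$data[, 2, ]) - mean(z_own$data[, 2, ])), 0.5)

  const <- tr
  const$data[, 2, ] <- 7
  expect_warning(sc2 <- fit_scaler(const), "zero-variance")
  z2 <- apply_scaler(sc2, const)
  expect_true(all(is.finite(z2$data)))
  expect_true(all(z2$data[, 2, ] == 0))
})

test_that("training follows the cosine schedule and is reproducible", {
  tensor <- toy_tensor(n = 16, C = 3, L = 12)
  cfg <- train_config(epochs = 5, seed = 4, class_weights = FALSE)
  m <- train_model(toy_spec("cnn1d", L = 12), tensor, cfg)
  expect_equal(nrow(m$history), 5)
  expect_equal(m$history$lr[1], 1e-3)
  expect_equal(m$history$lr[5], 1e-3 * 0.5 * (1 + cos(pi * 4 / 5)))

  one <- train_model(toy_spec("cnn1d", L = 12), tensor, train_config(epochs = 1, seed = 4))
  expect_equal(nrow(one$history), 1)

  m2 <- train_model(toy_spec("cnn1d", L = 12), tensor, cfg)
  expect_identical(m$history, m2$history)
  expect_equal(predict_proba(m, tensor), predict_proba(m2, tensor))

  # a separable toy is fit to perfect training accuracy
  sep <- toy_tensor(n = 64, C = 3, L = 40, shift = 3)
  fit <- train_model(toy_spec("tiny_fcn", L = 40), sep,
                     train_config(epochs = 30, seed = 2, class_weights = FALSE))
  acc <- mean((predict_proba(fit, sep)[, 2] >= 0.5) == (sep$labels == 1))
  expect_equal(acc, 1)

  # corrupted input aborts with a diagnostic instead of silently diverging
  bad <- tensor
  bad$data[1, 1, 1] <- NaN
  expect_error(
    train_model(toy_spec("cnn1d", L = 12), bad, train_config(epochs = 2, seed = 1, class_weights = FALSE)),
    "diverged"
  )
})

test_that("metrics match hand-computed confusion tables", {
  perfect <- evaluate(cbind(c(1, 0), c(0, 1)), labels = c(0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$f1, 1)

  flat <- evaluate(matrix(0.5, 10, 2), labels = rep(0:1, 5))
  expect_equal(flat$auc, 0.5)

  # TP=2, FN=1, TN=10, FP=3
  y <- rep(c(1, 1, 1, 0, 0), c(2, 0, 1, 10, 3))
  y <- c(rep(1, 3), rep(0, 13))
  p1 <- c(0.9, 0.8, 0.2, rep(0.1, 10), rep(0.7, 3))
  m <- evaluate(cbind(1 - p1, p1), labels = y)
  expect_equal(m$tp, 2); expect_equal(m$fn, 1)
  expect_equal(m$tn, 10); expect_equal(m$fp, 3)
  expect_equal(m$accuracy, 12 / 16)
  expect_equal(m$precision, 0.4)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m$balanced_accuracy, (2 / 3 + 10 / 13) / 2, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.4 * (2 / 3) / (0.4 + 2 / 3), tolerance = 1e-12)

  # accuracy equals balanced accuracy on class-balanced test sets
  set.seed(8)
  yb <- rep(0:1, each = 20)
  pb <- stats::runif(40)
  mb <- evaluate(cbind(1 - pb, pb), labels = yb)
  expect_lt(abs(mb$accuracy - mb$balanced_accuracy), 1e-9)

  expect_error(evaluate(matrix(numeric(), 0, 2), labels = integer()), "empty")
})

test_that("the rank-statistic AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- stats::rnorm(40) + y
    expect_equal(
      auc_rank(s, y),
      as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
      tolerance = 1e-12
    )
  }
  expect_true(is.na(auc_rank(stats::runif(5), rep(1, 5))))
})

test_that("cross-validation averages folds and guards against leakage", {
  tensor <- toy_tensor(n = 40, C = 3, L = 12, shift = 0)
  # 4 trips per participant so folds hold whole participants
  tensor$participant_ids <- sprintf("P%02d", rep(1:10, each = 4))
  tensor$labels <- as.integer(rep(rep(0:1, c(6, 4)), each = 4))
  tensor$data[tensor$labels == 1, 1, ] <- tensor$data[tensor$labels == 1, 1, ] + 3
  cfg <- train_config(epochs = 30, seed = 3)
  cv <- cross_validate(toy_spec("cnn1d", L = 12), tensor, cfg, k = 3)
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(cv$summary$accuracy, mean(cv$per_fold$accuracy))
  expect_equal(nrow(cv$predictions), 40) # every trip predicted exactly once
  expect_gt(cv$summary$auc, 0.9) # strong signal is recovered

  g <- glance(cv)
  expect_equal(g$model, "cnn1d")
  expect_equal(nrow(tidy(cv)), 3 * 6)

  bad_folds <- make_folds(unique(tensor$participant_ids), rep(0:1, c(6, 4)), k = 3, seed = 1)
  bad_folds[[1]]$train <- c(bad_folds[[1]]$train, bad_folds[[1]]$test[1])
  expect_error(cross_validate(toy_spec("cnn1d", L = 12), tensor, cfg, folds = bad_folds), "leakage")

  # with no class signal in the data, cross-validated AUC sits near chance
  aucs <- vapply(1:4, function(s) {
    null_tensor <- toy_tensor(n = 40, C = 3, L = 12, shift = 0, seed = 100 + s)
    null_tensor$participant_ids <- sprintf("P%02d", rep(1:10, each = 4))
    null_tensor$labels <- as.integer(rep(rep(0:1, c(6, 4)), each = 4))
    cfg_s <- train_config(epochs = 15, seed = s)
    cross_validate(toy_spec("cnn1d", L = 12), null_tensor, cfg_s, k = 3)$summary$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("the random-forest baseline runs under the same folds", {
  cleaned <- clean_cohort(generate_cohort(cohort_config(
    n_healthy = 4, n_mci = 3, trips_per_participant = c(2, 3),
    trip_duration_s = c(60, 100), turn_count_per_trip = c(1, 2),
    effect_size = 3, seed = 27
  )))
  features <- static_feature_table(cleaned)
  expect_equal(ncol(features), 17) # ids + label + 14 features
  res <- baseline_random_forest(features, k = 3, seed = 2, num_trees = 100)
  expect_true(all(res$per_fold$accuracy >= 0 & res$per_fold$accuracy <= 1))
  expect_equal(nrow(res$predictions), nrow(features))
})
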