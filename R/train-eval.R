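# Participant-stratified k-fold cross-validation with the unified training
# configuration used across all experiments: class-weighted cross-entropy,
# optional per-channel standard scaling fit on the training fold only, AdamW
# (lr 1e-3, weight decay 1e-4) with a cosine-annealing schedule whose period
# equals the number of epochs, batch size 32.

#' Training configuration
#'
#' @param lr Initial learning rate (default `1e-3`).
#' @param weight_decay Decoupled weight decay (default `1e-4`).
#' @param epochs Training epochs; also the cosine schedule period `T_max`.
#'   Default 200.
#' @param batch_size Mini-batch size (default 32).
#' @param class_weights Use inverse-frequency class weights (`TRUE`) or
#'   uniform weights (`FALSE`).
#' @param normalize Fit a per-channel standard scaler on the training fold
#'   and apply it to both folds.
#' @param seed Seed controlling parameter initialization and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-4, epochs = 200,
                         batch_size = 32, class_weights = TRUE,
                         normalize = FALSE, seed = 1L) {
  stopifnot_scalar_num(lr, "lr", 1e-12)
  stopifnot_scalar_num(weight_decay, "weight_decay", 0)
  stopifnot_scalar_num(epochs, "epochs", 1)
  stopifnot_scalar_num(batch_size, "batch_size", 1)
  structure(
    list(
      lr = lr, weight_decay = weight_decay, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      class_weights = isTRUE(class_weights), normalize = isTRUE(normalize),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Participant-stratified cross-validation folds
#'
#' Participants are split by diagnostic group, shuffled within group under
#' the seed, and dealt round-robin to the `k` folds, so every test set holds
#' a unique participant subset whose class ratio matches the cohort's within
#' rounding and no participant ever appears on both sides of a fold.
#'
#' @param participants Character vector of participant ids.
#' @param labels Labels aligned with `participants` (0/1 or
#'   `"healthy"`/`"mci"`).
#' @param k Number of folds (default 7).
#' @param seed Shuffle seed.
#' @return An object of class `fold_split`: list of `k` folds, each with
#'   `train` and `test` participant-id vectors.
#' @examples
#' make_folds(sprintf("P%02d", 1:21), rep(c(0, 1), c(14, 7)), k = 7, seed = 1)
#' @export
make_folds <- function(participants, labels, k = 7, seed = 1L) {
  if (length(participants) != length(labels)) abort("`participants` and `labels` lengths differ")
  if (anyDuplicated(participants)) abort("`participants` must be unique")
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2) abort("both classes must be present to stratify folds")
  if (length(participants) < k) abort("fewer participants than folds")
  assignment <- with_seed(seed, {
    out <- setNames(integer(length(participants)), participants)
    for (cls in c(0L, 1L)) {
      ids <- participants[y == cls]
      ids <- ids[sample.int(length(ids))]
      out[ids] <- (seq_along(ids) - 1L) %% k + 1L
    }
    out
  })
  folds <- lapply(seq_len(k), function(f) {
    list(
      train = participants[assignment[participants] != f],
      test = participants[assignment[participants] == f]
    )
  })
  structure(folds, class = "fold_split", k = k)
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "mci")
  } else {
    as.integer(labels)
  }
}

#' Inverse-frequency class weights
#'
#' `weight_c = n_total / (2 * n_c)`: a balanced training set gets `(1, 1)`,
#' the minority class is up-weighted proportionally.
#'
#' @param labels Training labels (0/1 or `"healthy"`/`"mci"`).
#' @return Named numeric vector `c(healthy = w0, mci = w1)`.
#' @examples
#' class_weights(rep(c(0, 1), c(30, 10))) # 0.667, 2
#' @export
class_weights <- function(labels) {
  y <- normalize_labels(labels)
  n <- length(y)
  n1 <- sum(y == 1)
  if (n1 == 0 || n1 == n) abort("both classes must be present in the training set")
  c(healthy = n / (2 * (n - n1)), mci = n / (2 * n1))
}

#' Fit / apply a per-channel standard scaler
#'
#' `fit_scaler()` computes per-channel mean and SD over all samples and
#' timesteps of a (training) tensor; `apply_scaler()` standardizes any
#' tensor with those statistics. Zero-variance channels get a unit divisor
#' with a warning.
#'
#' @param tensor A `series_tensor`.
#' @return `fit_scaler()`: an object of class `channel_scaler`;
#'   `apply_scaler()`: the standardized `series_tensor`.
#' @export
fit_scaler <- function(tensor) {
  d <- dim(tensor$data)
  mu <- numeric(d[2]); sdv <- numeric(d[2])
  for (c in seq_len(d[2])) {
    v <- tensor$data[, c, ]
    mu[c] <- mean(v)
    sdv[c] <- stats::sd(as.vector(v))
  }
  zero <- !is.finite(sdv) | sdv < 1e-12
  if (any(zero)) {
    warn(sprintf("%d zero-variance channel(s); using unit scale", sum(zero)))
    sdv[zero] <- 1
  }
  structure(list(mean = mu, sd = sdv), class = "channel_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `channel_scaler`.
#' @export
apply_scaler <- function(scaler, tensor) {
  d <- dim(tensor$data)
  for (c in seq_len(d[2])) {
    tensor$data[, c, ] <- (tensor$data[, c, ] - scaler$mean[c]) / scaler$sd[c]
  }
  tensor
}

# cosine annealing from lr to 0 over T_max epochs
cosine_lr <- function(lr0, epoch, t_max) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / t_max))
}

#' Train a classifier on a series tensor
#'
#' AdamW with decoupled weight decay and a cosine-annealed learning rate;
#' cross-entropy loss, optionally class-weighted. Reproducible for a fixed
#' `config$seed` on one CPU.
#'
#' @param spec A [model_spec()] (or an already built `mcidrive_model` whose
#'   weights are to be trained further).
#' @param tensor A `series_tensor` or `series_tensor_pair` carrying labels.
#' @param config A [train_config()].
#' @param stop_loss Optional early-exit threshold: training stops once the
#'   epoch mean loss falls below it (used by quick-convergence checks);
#'   `NULL` trains for the full schedule.
#' @return The trained `mcidrive_model` with a `history` tibble
#'   (`epoch`, `loss`, `lr`).
#' @export
train_model <- function(spec, tensor, config = train_config(), stop_loss = NULL) {
  model <- if (inherits(spec, "mcidrive_model")) spec else build_model(spec, seed = config$seed)
  check_tensor_spec(model, tensor)
  y <- tensor$labels
  n <- tensor_n(tensor)
  if (n < 2) abort("need at least 2 samples to train")
  cw <- if (config$class_weights) unname(class_weights(y)) else c(1, 1)
  layers <- model$param_layers
  history <- list()
  step <- 0L

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(config$lr, epoch, config$epochs)
      order <- sample.int(n)
      losses <- numeric()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- order[start:min(n, start + config$batch_size - 1L)]
        x <- model_input(model, tensor, idx)
        logits <- model_forward(model, x, training = TRUE)
        out <- softmax_xent(logits, y[idx], cw)
        if (!is.finite(out$loss)) {
          abort(sprintf(
            "training diverged: non-finite loss at epoch %d (lr %.2e); inspect scaling or lower the learning rate",
            epoch, lr
          ))
        }
        zero_grads(layers)
        model_backward(model, out$dlogits)
        step <- step + 1L
        adamw_step(layers, lr, config$weight_decay, step)
        losses <- c(losses, out$loss)
      }
      history[[epoch]] <- tibble(epoch = epoch, loss = mean(losses), lr = lr)
      if (!is.null(stop_loss) && mean(losses) < stop_loss) break
    }
  })

  model$history <- bind_rows(history)
  model$trained <- TRUE
  model$config <- config
  model
}

#' Evaluation metrics for binary predictions
#'
#' Computes accuracy, balanced accuracy (mean of per-class recalls), AUC
#' (rank statistic over the positive-class probabilities), precision, recall
#' and F1, plus the confusion counts, at a decision threshold on the
#' MCI-class probability.
#'
#' @param probs `N x 2` probability matrix (or an `mcidrive_model`, in which
#'   case `tensor` is predicted first).
#' @param labels True labels (0/1); defaults to the tensor's labels when a
#'   model + tensor is given.
#' @param threshold Decision threshold on the positive-class probability
#'   (default 0.5).
#' @param tensor Evaluation tensor when `probs` is a model.
#' @return A one-row `metrics_report` tibble: `accuracy`,
#'   `balanced_accuracy`, `auc`, `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `tn`, `fn`, `n`. AUC is `NA` when only one class is present.
#' @examples
#' evaluate(matrix(c(0.2, 0.8, 0.9, 0.1), 2, byrow = TRUE), labels = c(1, 0))
#' @export
evaluate <- function(probs, labels = NULL, threshold = 0.5, tensor = NULL) {
  if (inherits(probs, "mcidrive_model")) {
    if (is.null(tensor)) abort("`tensor` is required when evaluating a model")
    if (is.null(labels)) labels <- tensor$labels
    probs <- predict_proba(probs, tensor)
  }
  y <- normalize_labels(labels)
  if (length(y) == 0) abort("empty test set")
  p1 <- probs[, 2]
  pred <- as.integer(p1 >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  recall_pos <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  recall_neg <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall_pos) && precision + recall_pos > 0) {
    2 * precision * recall_pos / (precision + recall_pos)
  } else {
    NA_real_
  }
  out <- tibble(
    accuracy = (tp + tn) / length(y),
    balanced_accuracy = mean(c(recall_pos, recall_neg)),
    auc = auc_rank(p1, y),
    precision = precision, recall = recall_pos, f1 = f1,
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(y)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Area under the ROC curve via the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores Predicted positive-class scores.
#' @param labels True 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  y <- normalize_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Participant-stratified cross-validation of a model specification
#'
#' For each fold: subset the tensor by participant, optionally fit the
#' scaler on the training subset and standardize both sides, compute class
#' weights on the training labels, train a freshly initialized model and
#' evaluate it on the held-out participants' trips. Fold metrics are
#' averaged unweighted; folds whose test set holds a single class
#' contribute no AUC (undefined rank statistic).
#'
#' @param spec A [model_spec()].
#' @param tensor A `series_tensor` or `series_tensor_pair`.
#' @param config A [train_config()].
#' @param folds A `fold_split` from [make_folds()]; built automatically
#'   (with `config$seed`) when omitted.
#' @param k Folds when `folds` is omitted.
#' @return An object of class `cv_result`: list with `summary` (fold-mean
#'   metrics tibble), `per_fold`, `predictions` (pooled test-trip
#'   probabilities) and `folds`.
#' @export
cross_validate <- function(spec, tensor, config = train_config(), folds = NULL, k = 7) {
  pids <- tensor$participant_ids
  labels <- tensor$labels
  if (is.null(folds)) {
    plab <- tibble(participant_id = pids, label = labels) %>% distinct()
    folds <- make_folds(plab$participant_id, plab$label, k = k, seed = config$seed)
  }
  # hard leakage guard, not a convention
  for (f in folds) {
    if (length(intersect(f$train, f$test)) > 0) abort("fold leakage: train and test share participants")
  }

  subset_tensor <- function(tensor, idx) {
    if (inherits(tensor, "series_tensor_pair")) {
      out <- tensor
      out$trip <- subset_tensor(tensor$trip, idx)
      out$turn <- subset_tensor(tensor$turn, idx)
      out$labels <- tensor$labels[idx]
      out$participant_ids <- tensor$participant_ids[idx]
      out$trip_ids <- tensor$trip_ids[idx]
      out
    } else {
      new_series_tensor(
        tensor$data[idx, , , drop = FALSE], tensor$labels[idx],
        tensor$participant_ids[idx], tensor$trip_ids[idx], tensor$mode,
        mask = tensor$mask[idx]
      )
    }
  }

  per_fold <- list()
  preds <- list()
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    tr_idx <- which(pids %in% f$train)
    te_idx <- which(pids %in% f$test)
    res <- tryCatch({
      tr <- subset_tensor(tensor, tr_idx)
      te <- subset_tensor(tensor, te_idx)
      if (config$normalize) {
        if (inherits(tensor, "series_tensor_pair")) {
          sc1 <- fit_scaler(tr$trip); sc2 <- fit_scaler(tr$turn)
          tr$trip <- apply_scaler(sc1, tr$trip); te$trip <- apply_scaler(sc1, te$trip)
          tr$turn <- apply_scaler(sc2, tr$turn); te$turn <- apply_scaler(sc2, te$turn)
        } else {
          sc <- fit_scaler(tr)
          tr <- apply_scaler(sc, tr); te <- apply_scaler(sc, te)
        }
      }
      fold_config <- config
      fold_config$seed <- config$seed + i
      model <- train_model(spec, tr, fold_config)
      probs <- predict_proba(model, te)
      metrics <- evaluate(probs, labels = te$labels)
      list(metrics = metrics, probs = probs, te_idx = te_idx)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("fold %d failed: %s", i, conditionMessage(res)))
      next
    }
    per_fold[[length(per_fold) + 1]] <- mutate(res$metrics, fold = i, .before = 1)
    preds[[length(preds) + 1]] <- tibble(
      fold = i,
      participant_id = pids[res$te_idx],
      trip_id = tensor$trip_ids[res$te_idx],
      label = labels[res$te_idx],
      prob_mci = res$probs[, 2]
    )
  }
  if (length(per_fold) == 0) abort("all folds failed")
  per_fold <- bind_rows(per_fold)
  metric_cols <- c("accuracy", "balanced_accuracy", "auc", "precision", "recall", "f1")
  summary <- per_fold %>%
    summarise(across(all_of(metric_cols), ~ mean(.x, na.rm = TRUE)))
  structure(
    list(
      summary = summary, per_fold = per_fold,
      predictions = bind_rows(preds), folds = folds,
      spec = spec, config = config
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s over %d folds | accuracy %.3f, balanced accuracy %.3f, AUC %.3f\n",
    x$spec$family, nrow(x$per_fold),
    x$summary$accuracy, x$summary$balanced_accuracy, x$summary$auc
  ))
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Long tibble: `fold`, `metric`, `value`.
#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) {
  x$per_fold %>%
    tidyr::pivot_longer(
      all_of(c("accuracy", "balanced_accuracy", "auc", "precision", "recall", "f1")),
      names_to = "metric", values_to = "value"
    ) %>%
    select(all_of(c("fold", "metric", "value")))
}

#' One-row summary of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble with the fold-averaged metrics plus model and
#'   configuration descriptors.
#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  mutate(
    x$summary,
    model = x$spec$family, dual = x$spec$dual,
    attention = x$spec$attention,
    normalize = x$config$normalize, class_weights = x$config$class_weights,
    k = length(x$folds), epochs = x$config$epochs
  )
}

#' Tidy a trained model's loss history
#'
#' @param x An `mcidrive_model` returned by [train_model()].
#' @param ... Unused.
#' @return The `history` tibble (`epoch`, `loss`, `lr`).
#' @exportS3Method generics::tidy
tidy.mcidrive_model <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history")
  x$history
}

#' One-row summary of a trained model
#'
#' @param x An `mcidrive_model`.
#' @param ... Unused.
#' @return Tibble with family, parameter count, epochs trained and final
#'   loss.
#' @exportS3Method generics::glance
glance.mcidrive_model <- function(x, ...) {
  tibble(
    family = x$spec$family, dual = x$spec$dual,
    n_parameters = n_parameters(x$param_layers),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else x$history$loss[nrow(x$history)]
  )
}
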