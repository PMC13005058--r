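# Nontemporal reference baseline: a random forest on the 14 static summary
# features (per-trip mean and SD of the seven raw sensor channels),
# evaluated under the same participant-stratified folds as the deep models.

#' Build the static-feature table of a cleaned cohort
#'
#' @param cleaned A `cleaned_cohort`.
#' @return Tibble with `participant_id`, `trip_id`, `label` and the 14
#'   static feature columns.
#' @export
static_feature_table <- function(cleaned) {
  rows <- lapply(cleaned$trips, function(tr) {
    mutate(
      static_features(tr),
      participant_id = tr$participant_id, trip_id = tr$trip_id,
      label = label_of(tr$label), .before = 1
    )
  })
  bind_rows(rows)
}

#' Cross-validate the random-forest static-feature baseline
#'
#' @param features Output of [static_feature_table()].
#' @param folds A `fold_split`; built from the feature table's participants
#'   when omitted.
#' @param k,seed Fold parameters when `folds` is omitted.
#' @param num_trees Forest size (default 500).
#' @return A `cv_result`-like list with `summary`, `per_fold` and
#'   `predictions`.
#' @export
baseline_random_forest <- function(features, folds = NULL, k = 7, seed = 1L,
                                   num_trees = 500) {
  feat_cols <- setdiff(names(features), c("participant_id", "trip_id", "label"))
  if (is.null(folds)) {
    plab <- features %>% select(all_of(c("participant_id", "label"))) %>% distinct()
    folds <- make_folds(plab$participant_id, plab$label, k = k, seed = seed)
  }
  per_fold <- list()
  preds <- list()
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    tr <- features[features$participant_id %in% f$train, ]
    te <- features[features$participant_id %in% f$test, ]
    if (nrow(te) == 0 || length(unique(tr$label)) < 2) next
    fit <- with_seed(seed + i, randomForest::randomForest(
      x = as.data.frame(tr[feat_cols]), y = factor(tr$label, levels = c(0, 1)),
      ntree = num_trees
    ))
    p <- stats::predict(fit, as.data.frame(te[feat_cols]), type = "prob")[, "1"]
    per_fold[[length(per_fold) + 1]] <-
      mutate(evaluate(cbind(1 - p, p), labels = te$label), fold = i, .before = 1)
    preds[[length(preds) + 1]] <- tibble(
      fold = i, participant_id = te$participant_id, trip_id = te$trip_id,
      label = te$label, prob_mci = p
    )
  }
  per_fold <- bind_rows(per_fold)
  metric_cols <- c("accuracy", "balanced_accuracy", "auc", "precision", "recall", "f1")
  list(
    summary = per_fold %>% summarise(across(all_of(metric_cols), ~ mean(.x, na.rm = TRUE))),
    per_fold = per_fold,
    predictions = bind_rows(preds),
    folds = folds
  )
}
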