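test_that("risk scores are per-participant flag proportions", {
  preds <- tibble::tibble(
    participant_id = c("A", "A", "A", "B", "B"),
    pred = c(1, 1, 1, 1, 0),
    label = c(1, 1, 1, 0, 0)
  )
  r <- risk_score(preds)
  expect_equal(r$risk_score[r$participant_id == "A"], 1)
  expect_equal(r$risk_score[r$participant_id == "B"], 0.5)
  expect_true(all(r$risk_score >= 0 & r$risk_score <= 1))

  # an MCI driver misclassified on 2 of 3 trips: risk 1/3, trip accuracy 1/3
  sporadic <- tibble::tibble(
    participant_id = rep("C", 3), pred = c(1, 0, 0), label = rep(1, 3)
  )
  rc <- risk_score(sporadic)
  expect_equal(rc$risk_score, 1 / 3, tolerance = 1e-12)
  expect_equal(rc$trip_accuracy, 1 / 3, tolerance = 1e-12)
  # ... which the 10% threshold flags but a majority vote misses
  rc <- majority_vote(apply_thresholds(rc))
  expect_true(rc$flag_0.1)
  expect_false(rc$flag_0.5)
  expect_false(rc$majority_impaired)

  expect_error(risk_score(tibble::tibble(participant_id = "A", pred = NA)), "prediction")
})

test_that("threshold flags are monotone and boundary-exact", {
  r <- risk_score(tibble::tibble(
    participant_id = rep(c("A", "B", "C"), each = 10),
    pred = c(rep(1, 10), rep(c(1, 0), 5), rep(0, 10)),
    label = c(rep(1, 20), rep(0, 10))
  ))
  rt <- apply_thresholds(r, thresholds = c(0.1, 0.5, 1))
  # lowering the threshold never unflags
  expect_true(all(rt$flag_0.5 <= rt$flag_0.1))
  expect_true(all(rt$flag_1 <= rt$flag_0.5))
  # threshold 1.0 flags only risk exactly 1
  expect_identical(rt$flag_1, rt$risk_score == 1)
  expect_error(apply_thresholds(r, thresholds = 0), "0, 1")
})

test_that("majority vote equals thresholding at 0.5 with ties toward impaired", {
  # exhaustive over all trip counts up to 10 and all flag counts
  for (n in 1:10) {
    for (k in 0:n) {
      preds <- tibble::tibble(
        participant_id = rep("X", n), pred = rep(c(1, 0), c(k, n - k))
      )
      r <- majority_vote(apply_thresholds(risk_score(preds), 0.5))
      expect_identical(r$majority_impaired, r$flag_0.5)
      expect_identical(r$majority_impaired, k / n >= 0.5)
    }
  }
})

test_that("the threshold curve matches a brute-force sweep and is monotone", {
  set.seed(23)
  r <- risk_score(tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:12), each = 6),
    pred = rbinom(72, 1, rep(c(0.35, 0.05), c(30, 42))),
    label = rep(c(1, 0), c(30, 42))
  ))
  grid <- seq(0, 1, length.out = 101)
  curve <- threshold_curve(r, grid)
  expect_true(all(diff(curve$sensitivity) <= 1e-12))
  expect_equal(curve$sensitivity[1], 1) # threshold 0 flags everyone

  # a threshold just above the maximum risk flags no one
  capped <- r
  capped$risk_score <- pmin(capped$risk_score, 0.8)
  just_above <- threshold_curve(capped, thresholds = 0.81)
  expect_equal(just_above$sensitivity, 0)
  expect_equal(just_above$n_flagged, 0)

  # brute-force oracle over participant risk values
  for (i in c(1, 25, 50, 75, 101)) {
    t <- grid[i]
    expect_equal(curve$sensitivity[i], mean(r$risk_score[r$label == 1] >= t))
    expect_equal(curve$specificity[i], mean(r$risk_score[r$label == 0] < t))
  }

  single <- r[r$label == 1, ]
  expect_error(threshold_curve(single), "both classes")
})

test_that("low-threshold flagging beats majority vote on sporadic cohorts", {
  # trip-level predictions emulate a plausible classifier (sens .75/spec .9)
  # applied to ground-truth impairment expressed on 30% of MCI trips
  gains <- vapply(1:3, function(seed) {
    set.seed(seed)
    cohort <- generate_cohort(cohort_config(
      n_healthy = 8, n_mci = 6, trips_per_participant = c(5, 10),
      trip_duration_s = c(60, 80), turn_count_per_trip = c(1, 1),
      impaired_trip_fraction = 0.3, seed = seed * 100
    ))
    trips <- cohort$trips
    pred <- ifelse(trips$impaired, rbinom(nrow(trips), 1, 0.75), rbinom(nrow(trips), 1, 0.1))
    labels <- cohort$participants$label[match(trips$participant_id, cohort$participants$participant_id)]
    r <- majority_vote(apply_thresholds(risk_score(tibble::tibble(
      participant_id = trips$participant_id, pred = pred, label = labels
    ))))
    sum(r$flag_0.1[r$label == 1]) - sum(r$majority_impaired[r$label == 1])
  }, numeric(1))
  expect_true(all(gains > 0))
})

test_that("plot methods return ggplot objects", {
  r <- risk_score(tibble::tibble(
    participant_id = rep(c("A", "B"), each = 4),
    pred = c(1, 1, 0, 1, 0, 0, 0, 1),
    label = rep(c(1, 0), each = 4)
  ))
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  expect_s3_class(ggplot2::autoplot(threshold_curve(r)), "ggplot")
})
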