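test_that("degenerate and deterministic generation behave by construction", {
  empty <- generate_cohort(cohort_config(n_healthy = 0, n_mci = 0))
  expect_equal(nrow(empty$participants), 0)
  expect_equal(nrow(empty$trips), 0)

  cfg <- tiny_cohort_config(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_cohort_csv(generate_cohort(cfg), d1)
  export_cohort_csv(generate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted corners are recovered by the full turn-extraction path", {
  cfg <- cohort_config(
    n_healthy = 3, n_mci = 0, trips_per_participant = c(2, 2),
    trip_duration_s = c(180, 260), turn_count_per_trip = c(3, 3),
    effect_size = 1, seed = 31
  )
  cleaned <- clean_cohort(generate_cohort(cfg))
  n_peaks <- 0
  n_matched <- 0
  n_trips <- 0
  for (tr in cleaned$trips) {
    m <- tr$merged_1hz
    proj <- projection_params(ref_lat_rad = mean(m$lat) * pi / 180)
    xy <- latlon_to_xy(m$lat * pi / 180, m$lon * pi / 180, proj)
    peaks <- detect_turn_peaks(as.matrix(xy), m$speed)
    planted <- round(tr$corner_times) + 1
    # independent confirmation via the brute-force heading-change oracle
    oracle <- oracle_corners(as.matrix(xy))
    expect_true(all(vapply(peaks, function(p) min(abs(oracle - p)) <= 3, logical(1))))
    n_trips <- n_trips + 1
    n_peaks <- n_peaks + length(peaks)
    n_matched <- n_matched + sum(vapply(planted, function(ct) any(abs(peaks - ct) <= 3), logical(1)))
  }
  expect_equal(n_peaks / n_trips, 3, tolerance = 0.2)
  expect_gte(n_matched / (3 * n_trips), 0.9)
})

test_that("null cohorts are exchangeable and the impairment signature is recoverable", {
  # effect 1 / fraction 0: per-trip summary features of the two groups come
  # from the same process
  n_reject <- 0
  n_total <- 0
  for (seed in 1:3) {
    cfg <- cohort_config(
      n_healthy = 8, n_mci = 8, trips_per_participant = c(3, 3),
      trip_duration_s = c(60, 120), turn_count_per_trip = c(1, 2),
      effect_size = 1, impaired_trip_fraction = 0, seed = seed
    )
    cleaned <- clean_cohort(generate_cohort(cfg))
    feats <- static_feature_table(cleaned)
    for (col in setdiff(names(feats), c("participant_id", "trip_id", "label"))) {
      p <- suppressWarnings(
        stats::ks.test(feats[[col]][feats$label == 0], feats[[col]][feats$label == 1])$p.value
      )
      n_total <- n_total + 1
      if (p < 0.01) n_reject <- n_reject + 1
    }
  }
  expect_gte(1 - n_reject / n_total, 0.95)

  # effect >= 2, fraction 1: within-turn yaw-rate SD separates the groups
  cfg <- cohort_config(
    n_healthy = 5, n_mci = 5, trips_per_participant = c(3, 3),
    trip_duration_s = c(100, 160), turn_count_per_trip = c(2, 2),
    effect_size = 2.5, impaired_trip_fraction = 1, seed = 9
  )
  cohort <- generate_cohort(cfg)
  turn_sd <- function(i) {
    g <- cohort$trips$gyro[[i]]
    t_rel <- g$time - g$time[1]
    idx <- unlist(lapply(cohort$trips$corner_times[[i]], function(tau) {
      which(abs(t_rel - tau) <= 15 & abs(t_rel - tau) > 4) # jitter region, off the pulse
    }))
    stats::sd(g$gyro_z[idx])
  }
  sds <- vapply(seq_len(nrow(cohort$trips)), turn_sd, numeric(1))
  mci <- sds[cohort$trips$impaired]
  healthy <- sds[!cohort$trips$impaired]
  pairs <- outer(mci, healthy, ">")
  expect_gt(mean(pairs), 0.9)
})

test_that("GPS/IMU length ratio matches the configured rates on clean trips", {
  cohort <- generate_cohort(tiny_cohort_config(seed = 3))
  for (i in seq_len(nrow(cohort$trips))) {
    expect_lte(
      abs(nrow(cohort$trips$accel[[i]]) - 24 * nrow(cohort$trips$gps[[i]])), 1
    )
  }
})

test_that("malfunction injection follows the configured rates and seed", {
  cohort <- generate_cohort(tiny_cohort_config(seed = 5))
  expect_identical(inject_malfunctions(cohort, list()), cohort)

  dropped <- inject_malfunctions(cohort, list(drop_trip = c(gyro = 1)), seed = 2)
  expect_true(all(vapply(dropped$trips$gyro, is.null, logical(1))))
  expect_false(any(vapply(dropped$trips$gps, is.null, logical(1))))
  expect_identical(dropped$trips$impaired, cohort$trips$impaired)

  a <- inject_malfunctions(cohort, list(cutoff = 0.4, missing = 0.3), seed = 11)
  b <- inject_malfunctions(cohort, list(cutoff = 0.4, missing = 0.3), seed = 11)
  expect_identical(a, b)
  n_cut <- sum(vapply(seq_len(nrow(cohort$trips)), function(i) {
    nrow(a$trips$accel[[i]]) < nrow(cohort$trips$accel[[i]])
  }, logical(1)))
  expect_gt(n_cut, 0)
})

test_that("CSV export has the documented layout and round-trips losslessly", {
  cfg <- cohort_config(
    n_healthy = 1, n_mci = 0, trips_per_participant = c(2, 2),
    trip_duration_s = c(60, 90), turn_count_per_trip = c(1, 1), seed = 13
  )
  cohort <- generate_cohort(cfg)
  root <- withr::local_tempdir()
  export_cohort_csv(cohort, root)
  files <- list.files(root, recursive = TRUE)
  expect_length(grep("^participant_P01/(gps|accel|gyro)/trip_[12]\\.csv$", files), 6)

  # export -> ingest -> export produces identical trees
  back <- read_cohort_csv(root)
  root2 <- withr::local_tempdir()
  export_cohort_csv(back, root2)
  expect_identical(list.files(root, recursive = TRUE), list.files(root2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(root, f)), readLines(file.path(root2, f)))
  }

  empty_root <- withr::local_tempdir()
  export_cohort_csv(generate_cohort(cohort_config(n_healthy = 0, n_mci = 0)), empty_root)
  expect_length(list.dirs(empty_root, recursive = FALSE), 0)
})
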