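test_that("the planar projection matches its closed form", {
  p0 <- projection_params(ref_lat_rad = 0)
  expect_equal(as.numeric(latlon_to_xy(0, 0, p0)), c(0, 0))
  expect_equal(latlon_to_xy(0, 1, p0)$x_km, 6371) # x = R * lambda * cos(0)
  expect_equal(latlon_to_xy(1e-3, 0, p0)$y_km, 6.371) # y = R * phi
  p45 <- projection_params(ref_lat_rad = pi / 4)
  expect_equal(latlon_to_xy(0, 1, p45)$x_km, 6371 * cos(pi / 4))
  expect_error(latlon_to_xy(2, 0, p0), "lat")
})

test_that("peak detection finds corners, skips stationary points, matches the oracle", {
  xy <- corner_path(n = 101, corner_at = 50)
  speed <- rep(10, 101)

  expect_length(detect_turn_peaks(cbind(1:100 * 0.01, 0), rep(10, 100)), 0)

  peaks <- detect_turn_peaks(xy, speed)
  expect_length(peaks, 1)
  expect_lte(abs(peaks - 50), 2)
  expect_lte(abs(peaks - oracle_corners(xy)), 2)

  # zero speed at the corner discards the candidate
  speed0 <- speed
  speed0[abs(seq_len(101) - 50) <= 2] <- 0
  expect_length(detect_turn_peaks(xy, speed0), 0)

  expect_length(detect_turn_peaks(xy[1:2, ], speed[1:2]), 0)
})

test_that("slope mode discards undefined-gradient points but finds the corner", {
  xy <- corner_path(n = 101, corner_at = 50, angle = pi / 3)
  p <- turn_params(mode = "slope")
  peaks <- detect_turn_peaks(xy, rep(10, 101), p)
  expect_length(peaks, 1)
  expect_lte(abs(peaks - 50), 2)

  # a due-north segment has dx = 0 everywhere: those candidates are discarded
  north <- cbind(rep(0, 60), 1:60 * 0.01)
  east <- cbind(1:40 * 0.01, 0.6)
  path <- rbind(north, east)
  heading_peaks <- detect_turn_peaks(path, rep(10, 100), turn_params())
  slope_peaks <- detect_turn_peaks(path, rep(10, 100), p)
  expect_length(heading_peaks, 1) # atan2 mode sees the 90-degree corner
  expect_length(slope_peaks, 0) # slope mode cannot, by its dx = 0 rule
})

test_that("raising the gradient threshold never increases the peak count", {
  # property asserted on paths whose maneuvers are separated by more than the
  # run-merging gap, the detector's operating regime on real trips
  cleaned <- clean_cohort(generate_cohort(cohort_config(
    n_healthy = 3, n_mci = 0, trips_per_participant = c(2, 2),
    trip_duration_s = c(140, 220), turn_count_per_trip = c(2, 4), seed = 41
  )))
  for (tr in cleaned$trips) {
    m <- tr$merged_1hz
    proj <- projection_params(ref_lat_rad = mean(m$lat) * pi / 180)
    xy <- as.matrix(latlon_to_xy(m$lat * pi / 180, m$lon * pi / 180, proj))
    counts <- vapply(
      c(0.09, 0.174533, 0.35, 0.7, 1.1, 1.6),
      function(thr) length(detect_turn_peaks(xy, m$speed, turn_params(gradient_threshold_rad = thr))),
      integer(1)
    )
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("adjacent candidate runs merge to their lower-median index", {
  expect_equal(merge_adjacent_peaks(c(100L, 101L, 102L)), 101L)
  expect_equal(merge_adjacent_peaks(c(10L, 11L, 40L)), c(10L, 40L))
  expect_equal(merge_adjacent_peaks(integer()), integer())
  expect_equal(merge_adjacent_peaks(c(1L, 2L, 3L, 4L)), 2L) # lower median of even run
  expect_equal(merge_adjacent_peaks(c(1L, 4L, 7L), gap = 3), 4L)
  expect_error(merge_adjacent_peaks(c(5L, 2L)), "sorted")
})

test_that("turn windows are 31 x 10 with interpolated edges and deterministic", {
  cohort <- generate_cohort(cohort_config(
    n_healthy = 1, n_mci = 0, trips_per_participant = c(1, 1),
    trip_duration_s = c(150, 150), turn_count_per_trip = c(2, 2), seed = 17
  ))
  cleaned <- clean_cohort(cohort)
  trip <- cleaned$trips[[1]]
  s <- nrow(trip$merged_1hz)

  seg <- extract_turn_window(trip, peak = 60)
  expect_equal(dim(seg$window), c(31, 10))
  expect_false(seg$truncated)
  expect_identical(colnames(seg$window), mcidrive:::CHANNELS_10)

  # edge truncation interpolates back to 31 rows, preserving endpoints
  seg5 <- extract_turn_window(trip, peak = 5)
  expect_true(seg5$truncated)
  expect_equal(dim(seg5$window), c(31, 10))
  full <- build_channel_set(trip)
  expect_equal(seg5$window[1, ], full[1, ])
  expect_equal(seg5$window[31, ], full[20, ])

  # identical merged tables give identical windows
  seg_b <- extract_turn_window(trip, peak = 60)
  expect_identical(seg$window, seg_b$window)

  short <- trip
  short$merged_1hz <- trip$merged_1hz[1, ]
  expect_error(extract_turn_window(short, 1), "too short")

  # every extracted turn of a cohort satisfies the shape/speed invariants
  turns <- extract_turns(cleaned)
  for (sg in turns$segments) {
    expect_equal(dim(sg$window), c(31, 10))
    expect_gt(trip$merged_1hz$speed[sg$peak_index], 0)
  }
  expect_equal(nrow(turns$manifest), length(turns$segments))
})
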