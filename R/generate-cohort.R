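# Synthetic naturalistic-driving cohort generator.
#
# Route model: 2-D waypoint polylines. A trip is a sequence of straight,
# roughly constant-speed segments joined by 60-120 degree corners. Heading is
# integrated from a yaw-rate series that carries a rectangular pulse at each
# corner (the planted turn) plus Gaussian jitter; position is integrated from
# speed and heading at the IMU rate. The impairment signature is a
# multiplicative inflation (`effect_size`) of the speed and yaw-rate
# fluctuation SD inside the +/-15 s window around each corner, expressed on a
# per-trip Bernoulli(`impaired_trip_fraction`) basis for MCI participants.

# arbitrary mid-latitude reference point for the local map and the epoch
# used to assign absolute timestamps
.MAP_REF <- list(lat0_deg = 33.42, lon0_deg = -111.94, epoch = 1677628800) # 2023-03-01 UTC
.EARTH_RADIUS_KM <- 6371

# fixed kinematic noise scales (healthy baseline), in SI units
.KIN <- list(
  sd_speed = 0.25,     # m/s, speed fluctuation
  sd_yaw = 0.02,       # rad/s, yaw-rate jitter
  sd_gyro_xy = 0.02,   # rad/s, roll/pitch rate noise
  sd_acc_xy = 0.10,    # m/s^2, accelerometer noise (X/Y on top of kinematics)
  sd_acc_z = 0.15,     # m/s^2, vertical accelerometer noise
  turn_ramp_s = 6,     # duration over which a corner's heading change unfolds
  min_segment_s = 35,  # minimum spacing between corners (>= turn window)
  half_window_s = 15   # impairment signature window half width around a corner
)

#' Generate a labeled synthetic driving cohort
#'
#' Produces per-participant, per-trip raw sensor streams (GPS at
#' `gps_rate_hz`, accelerometer and gyroscope at `imu_rate_hz`) with planted
#' turning maneuvers and, for MCI participants, a sporadically expressed
#' impairment signature (inflated within-turn speed/yaw fluctuation). The
#' output is deterministic for a fixed `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `raw_cohort`: a list with
#'   * `participants`: tibble (`participant_id`, `age`, `sex`, `label`),
#'   * `trips`: tibble with one row per trip carrying the three stream tibbles
#'     (`gps`, `accel`, `gyro`) as list columns, the ground-truth per-trip
#'     `impaired` indicator and the planted `corner_times` (for recovery
#'     tests only; the analysis pipeline never reads them),
#'   * `config`: the generating configuration.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_healthy = 1, n_mci = 1,
#'   trips_per_participant = c(2, 2), trip_duration_s = c(120, 180),
#'   turn_count_per_trip = c(2, 3), seed = 42
#' ))
#' cohort$trips$gps[[1]]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a `cohort_config`")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_healthy + config$n_mci
  participants <- tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    age = if (n) sample(65:85, n, replace = TRUE) else integer(),
    sex = if (n) sample(c("male", "female"), n, replace = TRUE) else character(),
    label = rep(c("healthy", "mci"), c(config$n_healthy, config$n_mci))
  )

  trips <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- participants$participant_id[i]
    label <- participants$label[i]
    n_trips <- sample_in_range(config$trips_per_participant)
    t0 <- .MAP_REF$epoch + (i - 1) * 30 * 86400
    rows <- vector("list", n_trips)
    for (k in seq_len(n_trips)) {
      dur <- round(runif(1, config$trip_duration_s[1], config$trip_duration_s[2]))
      impaired <- label == "mci" && runif(1) < config$impaired_trip_fraction
      trip <- synth_trip(
        start_time = t0, duration_s = dur,
        n_turns = sample_in_range(config$turn_count_per_trip),
        impaired = impaired, effect_size = config$effect_size,
        imu_rate = config$imu_rate_hz
      )
      rows[[k]] <- tibble(
        participant_id = pid, trip_id = k, impaired = impaired,
        gps = list(trip$gps), accel = list(trip$accel), gyro = list(trip$gyro),
        corner_times = list(trip$corner_times)
      )
      # inter-trip gap well above the 60 s segmentation threshold
      t0 <- t0 + dur + round(runif(1, 120, 1800))
    }
    trips[[i]] <- bind_rows(rows)
  }
  trips <- bind_rows(trips)
  if (nrow(trips) == 0) {
    trips <- tibble(
      participant_id = character(), trip_id = integer(), impaired = logical(),
      gps = list(), accel = list(), gyro = list(), corner_times = list()
    )
  }
  structure(
    list(participants = participants, trips = trips, config = config),
    class = "raw_cohort"
  )
}

sample_in_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  sample(seq(r[1], r[2]), 1)
}

# Synthesize one trip. Returns the three stream tibbles plus the planted
# corner times (seconds from trip start) as ground truth.
synth_trip <- function(start_time, duration_s, n_turns, impaired, effect_size,
                       imu_rate = 24) {
  n_gps <- as.integer(duration_s)
  min_seg <- .KIN$min_segment_s
  n_turns <- min(n_turns, max(0L, floor(n_gps / min_seg) - 1L))
  n_imu <- n_gps * imu_rate
  dt <- 1 / imu_rate
  t_rel <- (seq_len(n_imu) - 1) * dt

  # corner placement: n_turns + 1 segments, each at least `min_seg` seconds
  if (n_turns > 0) {
    props <- runif(n_turns + 1, 0.5, 1.5)
    seg <- min_seg + (n_gps - min_seg * (n_turns + 1)) * props / sum(props)
    corner_times <- cumsum(seg)[seq_len(n_turns)]
    corner_angles <- sample(c(-1, 1), n_turns, replace = TRUE) *
      runif(n_turns, 60, 120) * pi / 180
  } else {
    corner_times <- numeric()
    corner_angles <- numeric()
  }

  # within-turn fluctuation inflation for impaired trips
  sd_mult <- rep(1, n_imu)
  if (impaired && n_turns > 0) {
    for (tau in corner_times) {
      idx <- which(abs(t_rel - tau) <= .KIN$half_window_s)
      sd_mult[idx] <- effect_size
    }
  }

  # yaw rate: corner pulses + jitter
  yaw <- rnorm(n_imu, 0, .KIN$sd_yaw) * sd_mult
  for (j in seq_along(corner_times)) {
    idx <- which(abs(t_rel - corner_times[j]) <= .KIN$turn_ramp_s / 2)
    yaw[idx] <- yaw[idx] + corner_angles[j] / .KIN$turn_ramp_s
  }

  # speed: per-segment cruise level, slow-down through corners, jitter
  base_speed <- runif(max(1, n_turns + 1), 8, 15)
  seg_id <- if (n_turns > 0) findInterval(t_rel, corner_times) + 1 else rep(1L, n_imu)
  v <- base_speed[seg_id]
  for (tau in corner_times) {
    v <- v * (1 - 0.35 * exp(-((t_rel - tau) / 4)^2))
  }
  v <- as.numeric(stats::filter(v, rep(1 / (2 * imu_rate), 2 * imu_rate), sides = 2))
  ok <- which(!is.na(v))
  v[seq_len(ok[1] - 1)] <- v[ok[1]]
  if (ok[length(ok)] < n_imu) v[(ok[length(ok)] + 1):n_imu] <- v[ok[length(ok)]]
  v <- pmax(0.3, v + rnorm(n_imu, 0, .KIN$sd_speed) * sd_mult)

  # integrate heading and position (meters)
  heading <- runif(1, -pi, pi) + cumsum(yaw) * dt
  x_m <- cumsum(v * cos(heading)) * dt
  y_m <- cumsum(v * sin(heading)) * dt

  # IMU channels
  acc_x <- c(0, diff(v)) / dt + rnorm(n_imu, 0, .KIN$sd_acc_xy)
  acc_y <- v * yaw + rnorm(n_imu, 0, .KIN$sd_acc_xy)
  acc_z <- rnorm(n_imu, 0, .KIN$sd_acc_z)
  gyro_x <- rnorm(n_imu, 0, .KIN$sd_gyro_xy)
  gyro_y <- rnorm(n_imu, 0, .KIN$sd_gyro_xy)

  times <- start_time + t_rel
  gps_idx <- seq(1L, n_imu, by = imu_rate)
  lat0 <- .MAP_REF$lat0_deg * pi / 180
  r_m <- .EARTH_RADIUS_KM * 1000

  list(
    gps = tibble(
      time = start_time + (seq_len(n_gps) - 1),
      lat = .MAP_REF$lat0_deg + (y_m[gps_idx] / r_m) * 180 / pi,
      lon = .MAP_REF$lon0_deg + (x_m[gps_idx] / (r_m * cos(lat0))) * 180 / pi,
      speed = v[gps_idx]
    ),
    accel = tibble(
      time = times, acc_x = acc_x, acc_y = acc_y, acc_z = acc_z
    ),
    gyro = tibble(
      time = times, gyro_x = gyro_x, gyro_y = gyro_y, gyro_z = yaw
    ),
    corner_times = corner_times
  )
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat(sprintf(
    "<raw_cohort> %d participants (%d healthy, %d MCI), %d trips\n",
    nrow(x$participants),
    sum(x$participants$label == "healthy"),
    sum(x$participants$label == "mci"),
    nrow(x$trips)
  ))
  invisible(x)
}
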