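#' Configuration for the synthetic driving cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. The defaults
#' mirror the analyzed naturalistic-driving cohort this package emulates:
#' 12 cognitively healthy and 7 MCI drivers contributing between 3 and 46
#' retained trips each, recorded by a 1 Hz GPS and 24 Hz inertial sensors.
#'
#' @param n_healthy,n_mci Number of participants per diagnostic group.
#' @param trips_per_participant Integer range (length-2 vector) of trips each
#'   participant contributes.
#' @param trip_duration_s Range (seconds) of trip durations.
#' @param turn_count_per_trip Integer range of planted turning maneuvers per
#'   trip. The realized count is capped so that successive corners stay at
#'   least 35 s apart, keeping each turn window disjoint and detectable.
#' @param gps_rate_hz,imu_rate_hz Sampling rates of the GPS and the inertial
#'   (accelerometer/gyroscope) sensors. Defaults 1 and 24 Hz.
#' @param effect_size Multiplier (>= 1) on the within-turn speed and yaw-rate
#'   fluctuation standard deviation for impaired trips. `effect_size = 1`
#'   reproduces the null: both groups are statistically exchangeable.
#' @param impaired_trip_fraction Probability in `[0, 1]` that a given MCI
#'   participant's trip expresses the impairment signature, modeling the
#'   sporadic, day-to-day variability of mild cognitive impairment.
#' @param malfunction_rates Named list with probabilities `drop_trip` (a
#'   sensor's recording of a trip is missing entirely), `cutoff` (a sensor
#'   stops mid-trip) and `missing` (a trip contains blanked values).
#' @param seed Integer seed; all stochastic draws of the generator flow from
#'   one generator seeded once per cohort.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_healthy = 2, n_mci = 1, trips_per_participant = c(2, 3))
#' cfg$effect_size
#' @export
cohort_config <- function(n_healthy = 12,
                          n_mci = 7,
                          trips_per_participant = c(3, 46),
                          trip_duration_s = c(180, 900),
                          turn_count_per_trip = c(3, 10),
                          gps_rate_hz = 1,
                          imu_rate_hz = 24,
                          effect_size = 2.5,
                          impaired_trip_fraction = 1,
                          malfunction_rates = list(drop_trip = 0, cutoff = 0, missing = 0),
                          seed = 1L) {
  stopifnot_scalar_num(n_healthy, "n_healthy", 0)
  stopifnot_scalar_num(n_mci, "n_mci", 0)
  check_range <- function(r, name, lower) {
    if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < lower) {
      abort(sprintf("`%s` must be a non-decreasing length-2 numeric range with minimum >= %s", name, lower))
    }
  }
  check_range(trips_per_participant, "trips_per_participant", 0)
  check_range(trip_duration_s, "trip_duration_s", 40)
  check_range(turn_count_per_trip, "turn_count_per_trip", 0)
  stopifnot_scalar_num(gps_rate_hz, "gps_rate_hz", 1e-9)
  stopifnot_scalar_num(imu_rate_hz, "imu_rate_hz", 1e-9)
  stopifnot_scalar_num(effect_size, "effect_size", 1)
  stopifnot_scalar_num(impaired_trip_fraction, "impaired_trip_fraction", 0, 1)
  for (nm in c("drop_trip", "cutoff", "missing")) {
    if (is.null(malfunction_rates[[nm]])) malfunction_rates[[nm]] <- 0
    stopifnot_scalar_num(malfunction_rates[[nm]], paste0("malfunction_rates$", nm), 0, 1)
  }
  stopifnot_scalar_num(seed, "seed")

  structure(
    list(
      n_healthy = as.integer(n_healthy),
      n_mci = as.integer(n_mci),
      trips_per_participant = as.integer(round(trips_per_participant)),
      trip_duration_s = trip_duration_s,
      turn_count_per_trip = as.integer(round(turn_count_per_trip)),
      gps_rate_hz = gps_rate_hz,
      imu_rate_hz = imu_rate_hz,
      effect_size = effect_size,
      impaired_trip_fraction = impaired_trip_fraction,
      malfunction_rates = malfunction_rates[c("drop_trip", "cutoff", "missing")],
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf(
    "  participants: %d healthy + %d MCI | trips/participant: %d-%d\n",
    x$n_healthy, x$n_mci, x$trips_per_participant[1], x$trips_per_participant[2]
  ))
  cat(sprintf(
    "  trip duration: %g-%g s | turns/trip: %d-%d | rates: GPS %g Hz, IMU %g Hz\n",
    x$trip_duration_s[1], x$trip_duration_s[2],
    x$turn_count_per_trip[1], x$turn_count_per_trip[2],
    x$gps_rate_hz, x$imu_rate_hz
  ))
  cat(sprintf(
    "  effect size: %g | impaired trip fraction: %g | seed: %d\n",
    x$effect_size, x$impaired_trip_fraction, x$seed
  ))
  invisible(x)
}
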