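#' Inject sensor malfunctions into a raw cohort
#'
#' Emulates the failure modes seen with on-board telematics loggers: a sensor
#' failing to record a whole trip, stopping mid-trip, or producing blanked
#' values. Each (trip, sensor) pair is subjected independently to the three
#' failure draws; the ground-truth impairment indicators are left untouched.
#'
#' @param cohort A `raw_cohort` from [generate_cohort()].
#' @param rates Named list of probabilities: `drop_trip` (remove the sensor's
#'   recording of the trip), `cutoff` (truncate the stream at a uniform
#'   30-70% point) and `missing` (blank 2% of one random channel's rows).
#'   Each entry is either a single probability applied to every sensor or a
#'   named vector with per-sensor probabilities (names among `gps`, `accel`,
#'   `gyro`). Missing entries default to the cohort config's
#'   `malfunction_rates`.
#' @param seed Seed for the malfunction draws; defaults to `config$seed + 1`
#'   so injection is reproducible and independent of stream synthesis.
#' @return The modified `raw_cohort`. Dropped streams become `NULL` entries in
#'   the corresponding list column.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_healthy = 1, n_mci = 0, trips_per_participant = c(2, 2),
#'   trip_duration_s = c(120, 150), seed = 3
#' ))
#' broken <- inject_malfunctions(cohort, list(drop_trip = 1), seed = 9)
#' sum(vapply(broken$trips$gyro, is.null, logical(1)))
#' @export
inject_malfunctions <- function(cohort, rates = NULL, seed = NULL) {
  if (!inherits(cohort, "raw_cohort")) abort("`cohort` must be a `raw_cohort`")
  base <- cohort$config$malfunction_rates
  rates <- utils::modifyList(base, as.list(rates %||% list()))
  rate_for <- function(r, sensor) {
    r <- r %||% 0
    p <- if (length(r) > 1 || !is.null(names(r))) unname(r[sensor] %|NA|% 0) else r
    stopifnot_scalar_num(p, "malfunction rate", 0, 1)
  }
  if (is.null(seed)) seed <- cohort$config$seed + 1L
  if (all(unlist(rates) == 0) || nrow(cohort$trips) == 0) return(cohort)

  with_seed(seed, {
    trips <- cohort$trips
    sensors <- c("gps", "accel", "gyro")
    for (i in seq_len(nrow(trips))) {
      for (s in sensors) {
        stream <- trips[[s]][[i]]
        if (is.null(stream)) next
        if (runif(1) < rate_for(rates$drop_trip, s)) {
          trips[[s]][i] <- list(NULL)
          next
        }
        if (runif(1) < rate_for(rates$cutoff, s)) {
          keep <- max(2L, floor(nrow(stream) * runif(1, 0.3, 0.7)))
          stream <- stream[seq_len(keep), ]
        }
        if (runif(1) < rate_for(rates$missing, s)) {
          chans <- setdiff(names(stream), "time")
          ch <- sample(chans, 1)
          n_blank <- max(1L, ceiling(nrow(stream) * 0.02))
          stream[[ch]][sample.int(nrow(stream), n_blank)] <- NA_real_
        }
        trips[[s]][[i]] <- stream
      }
    }
    cohort$trips <- trips
    cohort
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

`%|NA|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
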