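# Turning-maneuver detection on the merged 1 Hz trip. GPS coordinates are
# projected to a local plane, candidate turn points are found where the path
# direction changes by more than a 10 degree (0.174533 rad) threshold between
# successive steps, stationary and degenerate points are discarded, runs of
# adjacent candidates are merged to their median index, and a fixed +/-15 s
# window (31 rows at 1 Hz) is cut around each surviving peak.

#' Local planar projection parameters
#'
#' @param earth_radius_km Earth radius in kilometers (default 6371).
#' @param ref_lat_rad Reference latitude in radians for the local
#'   equirectangular projection; conventionally the per-trip mean latitude.
#' @return An object of class `projection_params`.
#' @export
projection_params <- function(earth_radius_km = 6371, ref_lat_rad = 0) {
  stopifnot_scalar_num(earth_radius_km, "earth_radius_km", 1e-9)
  stopifnot_scalar_num(ref_lat_rad, "ref_lat_rad", -pi / 2, pi / 2)
  structure(
    list(earth_radius_km = earth_radius_km, ref_lat_rad = ref_lat_rad),
    class = "projection_params"
  )
}

#' Turn-detector parameters
#'
#' @param gradient_threshold_rad Angular-change threshold between successive
#'   path steps for a sample to count as a turn candidate. Default 0.174533
#'   rad (10 degrees).
#' @param half_window_s Half width of the extracted turn window in seconds
#'   (default 15, giving 31 rows at 1 Hz).
#' @param min_speed Candidates with speed less than or equal to this value
#'   (m/s) are discarded as stationary; default 0 (i.e. speed must be
#'   strictly positive).
#' @param adjacency_gap Maximum index gap for two candidates to be merged
#'   into the same run (default 2 samples).
#' @param mode `"heading"` (default) computes the direction change via
#'   `atan2` of the path increments; `"slope"` thresholds the change of the
#'   raw `dy/dx` slope angle and discards `dx = 0` points, reproducing the
#'   classical first-derivative formulation.
#' @return An object of class `turn_params`.
#' @export
turn_params <- function(gradient_threshold_rad = 0.174533,
                        half_window_s = 15,
                        min_speed = 0,
                        adjacency_gap = 2,
                        mode = c("heading", "slope")) {
  stopifnot_scalar_num(gradient_threshold_rad, "gradient_threshold_rad", 1e-12)
  stopifnot_scalar_num(half_window_s, "half_window_s", 1)
  stopifnot_scalar_num(min_speed, "min_speed", 0)
  stopifnot_scalar_num(adjacency_gap, "adjacency_gap", 0)
  structure(
    list(
      gradient_threshold_rad = gradient_threshold_rad,
      half_window_s = as.integer(half_window_s),
      min_speed = min_speed,
      adjacency_gap = as.integer(adjacency_gap),
      mode = match.arg(mode)
    ),
    class = "turn_params"
  )
}

#' Project latitude/longitude to local planar coordinates
#'
#' Local equirectangular projection: `x = R * lambda * cos(ref_lat)`,
#' `y = R * phi`, with angles in radians and `R` the Earth radius. Continuous
#' and invertible near the reference latitude; at city scale it is conformal
#' enough that angular-change thresholds on the projected path are preserved.
#'
#' @param lat_rad,lon_rad Latitude and longitude in radians (vectors).
#' @param params A [projection_params()].
#' @return A tibble with columns `x_km`, `y_km`.
#' @examples
#' latlon_to_xy(0, 1, projection_params()) # x = 6371 km on the equator
#' @export
latlon_to_xy <- function(lat_rad, lon_rad, params = projection_params()) {
  if (any(abs(lat_rad) > pi / 2 + 1e-12)) abort("|lat_rad| must be <= pi/2")
  tibble(
    x_km = params$earth_radius_km * lon_rad * cos(params$ref_lat_rad),
    y_km = params$earth_radius_km * lat_rad
  )
}

#' Detect turn peaks along a projected path
#'
#' Candidate samples are those where the change in path direction between
#' successive steps exceeds `gradient_threshold_rad`; samples with
#' non-positive speed are discarded (stationary GPS jitter), and in `"slope"`
#' mode samples with `dx = 0` (undefined slope) are discarded as well. Runs
#' of adjacent candidates are then collapsed to their median index by
#' [merge_adjacent_peaks()].
#'
#' @param xy Two-column matrix/data frame of planar coordinates (km), one row
#'   per 1 Hz sample.
#' @param speed Speed (m/s) per sample.
#' @param params A [turn_params()].
#' @return Sorted integer vector of peak row indices (possibly empty).
#' @export
detect_turn_peaks <- function(xy, speed, params = turn_params()) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(integer())
  if (length(speed) != n) abort("`speed` must have one value per path sample")
  dx <- diff(xy[, 1])
  dy <- diff(xy[, 2])
  if (params$mode == "heading") {
    ang <- atan2(dy, dx)
    dang <- wrap_angle(diff(ang))
    valid <- rep(TRUE, n - 2)
  } else {
    ang <- atan(dy / dx) # undefined (NaN/Inf handling) where dx == 0
    dang <- wrap_angle(diff(ang))
    valid <- dx[-1] != 0 & dx[-(n - 1)] != 0 & is.finite(dang)
  }
  # dang[i] is the direction change at sample i + 1
  cand <- which(valid & abs(dang) > params$gradient_threshold_rad) + 1L
  cand <- cand[speed[cand] > params$min_speed]
  merge_adjacent_peaks(cand, gap = params$adjacency_gap)
}

#' Merge runs of adjacent turn candidates to their median index
#'
#' Maximal runs of candidates whose successive index gaps are at most `gap`
#' collapse to the run's median index (lower median for even-length runs),
#' ensuring one peak per turn event.
#'
#' @param candidates Sorted integer indices.
#' @param gap Maximum gap (samples) within a run; default 2.
#' @return Sorted unique integer vector of merged peak indices.
#' @examples
#' merge_adjacent_peaks(c(100, 101, 102)) # 101
#' merge_adjacent_peaks(c(10, 11, 40)) # 10, 40
#' @export
merge_adjacent_peaks <- function(candidates, gap = 2) {
  candidates <- as.integer(candidates)
  if (length(candidates) == 0) return(integer())
  if (is.unsorted(candidates)) abort("`candidates` must be sorted")
  run_id <- cumsum(c(1L, as.integer(diff(candidates) > gap)))
  out <- vapply(split(candidates, run_id), function(run) {
    run[floor((length(run) + 1) / 2)] # lower median
  }, integer(1))
  sort(unique(unname(out)))
}

#' Extract a fixed-length 10-channel window around a turn peak
#'
#' Cuts `half_window_s` rows on either side of the peak from the trip's
#' 10-channel matrix (31 rows at the defaults). Windows truncated by the trip
#' boundary are linearly interpolated back to the standard length, preserving
#' their endpoints.
#'
#' @param trip A `trip_record` with `merged_1hz`.
#' @param peak Merged-row index of the turn peak.
#' @param params A [turn_params()].
#' @return An object of class `turn_segment`: list with `participant_id`,
#'   `trip_id`, `peak_index`, `truncated` and the `window` matrix
#'   (`2 * half_window_s + 1` rows, 10 channels).
#' @export
extract_turn_window <- function(trip, peak, params = turn_params()) {
  if (is.null(trip$merged_1hz) || nrow(trip$merged_1hz) < 2) abort("trip too short")
  chans <- build_channel_set(trip)
  s <- nrow(chans)
  if (peak < 1 || peak > s) abort("`peak` outside trip")
  len <- 2L * params$half_window_s + 1L
  lo <- max(1L, peak - params$half_window_s)
  hi <- min(s, peak + params$half_window_s)
  window <- chans[lo:hi, , drop = FALSE]
  truncated <- nrow(window) < len
  if (truncated) window <- interpolate_to_length(window, len)
  structure(
    list(
      participant_id = trip$participant_id, trip_id = trip$trip_id,
      peak_index = as.integer(peak), truncated = truncated, window = window
    ),
    class = "turn_segment"
  )
}

#' Detect and extract all turning maneuvers of a cleaned cohort
#'
#' Projects each trip's GPS track with a per-trip mean-latitude reference,
#' runs the peak detector and cuts one fixed-length window per peak.
#'
#' @param cleaned A `cleaned_cohort` from [clean_cohort()] (or a list of
#'   `trip_record`s).
#' @param params A [turn_params()].
#' @param earth_radius_km Earth radius used by the projection.
#' @return List with `segments` (list of `turn_segment`s) and `manifest`
#'   (tibble: `participant_id`, `trip_id`, `peak_index`, `truncated`).
#' @export
extract_turns <- function(cleaned, params = turn_params(), earth_radius_km = 6371) {
  trips <- if (inherits(cleaned, "cleaned_cohort")) cleaned$trips else cleaned
  segments <- list()
  manifest <- list()
  for (trip in trips) {
    m <- trip$merged_1hz
    proj <- projection_params(earth_radius_km, ref_lat_rad = mean(m$lat) * pi / 180)
    xy <- latlon_to_xy(m$lat * pi / 180, m$lon * pi / 180, proj)
    peaks <- detect_turn_peaks(as.matrix(xy), m$speed, params)
    for (p in peaks) {
      seg <- extract_turn_window(trip, p, params)
      segments[[length(segments) + 1]] <- seg
      manifest[[length(manifest) + 1]] <- tibble(
        participant_id = trip$participant_id, trip_id = trip$trip_id,
        peak_index = seg$peak_index, truncated = seg$truncated
      )
    }
  }
  list(
    segments = segments,
    manifest = if (length(manifest)) bind_rows(manifest) else tibble(
      participant_id = character(), trip_id = integer(),
      peak_index = integer(), truncated = logical()
    )
  )
}
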