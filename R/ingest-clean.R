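# Trip segmentation, cross-sensor completeness checks and 1 Hz
# synchronization. A trip is a maximal run of samples whose successive
# timestamp gaps stay within `gap_s` (default 60 s); gaps above the threshold
# start a new trip. After segmentation the three sensors are matched by
# timestamp overlap and merged onto the 1 Hz GPS grid by block-averaging the
# high-rate inertial samples falling into each GPS second.

#' Segment a continuous sensor stream into trips
#'
#' @param times Sorted numeric timestamps (seconds).
#' @param gap_s Gap threshold in seconds: a successive difference strictly
#'   greater than `gap_s` starts a new trip. Default 60 (1 minute).
#' @return A tibble with one row per trip: `trip`, `start`, `end` (index
#'   ranges into `times`). Empty input gives zero rows.
#' @examples
#' segment_trips(c(0:10, 100:105))
#' @export
segment_trips <- function(times, gap_s = 60) {
  if (length(times) == 0) {
    return(tibble(trip = integer(), start = integer(), end = integer()))
  }
  if (is.unsorted(times)) abort("`times` must be sorted")
  breaks <- which(diff(times) > gap_s)
  start <- c(1L, breaks + 1L)
  end <- c(breaks, length(times))
  tibble(trip = seq_along(start), start = start, end = end)
}

#' Flag per-participant trip-count mismatches across sensors
#'
#' @param trip_counts Named vector or list of per-sensor trip counts; the
#'   expected names are `gps`, `accel` and `gyro`. A missing sensor is
#'   treated as count 0 and flagged.
#' @return A one-row tibble: the three counts plus a logical `mismatch`.
#' @examples
#' check_mismatch(c(gps = 4, accel = 6, gyro = 6))
#' @export
check_mismatch <- function(trip_counts) {
  trip_counts <- unlist(trip_counts)
  sensors <- c("gps", "accel", "gyro")
  missing <- setdiff(sensors, names(trip_counts))
  counts <- setNames(rep(0L, 3L), sensors)
  counts[intersect(sensors, names(trip_counts))] <-
    as.integer(trip_counts[intersect(sensors, names(trip_counts))])
  tibble(
    gps = counts[["gps"]], accel = counts[["accel"]], gyro = counts[["gyro"]],
    mismatch = length(unique(counts)) > 1L || length(missing) > 0L
  )
}

#' Merge a trip's three sensor streams onto the 1 Hz GPS grid
#'
#' For every GPS second `g` the inertial channels are averaged over the block
#' of high-rate samples with timestamps in `[g, g + 1)`; ragged final blocks
#' are averaged over the samples available. Rows containing any missing value
#' (from either a blanked sensor value or a second without inertial coverage)
#' are dropped and the trip flagged.
#'
#' @param trip A `trip_record` list with `gps`, `accel` and `gyro` stream
#'   tibbles (as produced inside [clean_cohort()], or assembled by hand).
#' @return The `trip_record` with `merged_1hz` (tibble: `time`, `lat`, `lon`,
#'   `speed`, `acc_x/y/z`, `gyro_x/y/z`) and a character vector `flags`
#'   (`"missing_values"` when rows were dropped, `"incomplete"` when fewer
#'   than 2 rows survive).
#' @export
synchronize <- function(trip) {
  for (s in c("gps", "accel", "gyro")) {
    if (is.null(trip[[s]])) abort(sprintf("sensor `%s` missing; cannot synchronize", s))
  }
  gps <- trip$gps
  gsec <- floor(gps$time)

  block_means <- function(stream, chans) {
    grp <- match(floor(stream$time), gsec)
    keep <- !is.na(grp)
    out <- matrix(NA_real_, nrow(gps), length(chans), dimnames = list(NULL, chans))
    if (any(keep)) {
      grp <- grp[keep]
      cnt <- tabulate(grp, nbins = nrow(gps))
      for (ch in chans) {
        sums <- rowsum(stream[[ch]][keep], grp, reorder = FALSE)
        idx <- as.integer(rownames(sums))
        out[idx, ch] <- sums[, 1] / cnt[idx]
      }
    }
    out
  }

  acc <- block_means(trip$accel, c("acc_x", "acc_y", "acc_z"))
  gyr <- block_means(trip$gyro, c("gyro_x", "gyro_y", "gyro_z"))
  merged <- tibble(
    time = gps$time, lat = gps$lat, lon = gps$lon, speed = gps$speed,
    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
    gyro_x = gyr[, 1], gyro_y = gyr[, 2], gyro_z = gyr[, 3]
  )
  complete <- stats::complete.cases(merged)
  flags <- character()
  if (any(!complete)) flags <- c(flags, "missing_values")
  merged <- merged[complete, ]
  if (nrow(merged) < 2) flags <- c(flags, "incomplete")
  trip$merged_1hz <- merged
  trip$flags <- flags
  trip
}

#' Clean a raw cohort into synchronized 1 Hz trip records
#'
#' Runs the full cleaning funnel: per-sensor re-segmentation of each
#' participant's continuous stream, the cross-sensor trip-count mismatch
#' check, timestamp-overlap matching of trips across sensors, 1 Hz
#' synchronization, and exclusion of incomplete or too-short trips. Only
#' trips passing every check are retained; every exclusion is logged exactly
#' once with its reason.
#'
#' @param x A `raw_cohort` or a path to a CSV tree readable by
#'   [read_cohort_csv()].
#' @param gap_s Trip segmentation gap threshold (seconds), default 60.
#' @param min_rows Minimum merged rows for a trip to support analysis;
#'   default 30 (one turn window). Shorter trips are excluded.
#' @return An object of class `cleaned_cohort`: list with
#'   * `trips`: list of `trip_record`s, each carrying `merged_1hz`,
#'   * `manifest`: tibble (`participant_id`, `trip_id`, `n_rows`, `label`,
#'     `impaired`, `flags`),
#'   * `exclusions`: tibble (`participant_id`, `trip_id`, `reason`),
#'   * `mismatch`: per-participant sensor trip counts with mismatch flags,
#'   * `participants`: the label table.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_healthy = 1, n_mci = 1, trips_per_participant = c(2, 2),
#'   trip_duration_s = c(120, 150), seed = 5
#' ))
#' cleaned <- clean_cohort(cohort)
#' cleaned$manifest
#' @export
clean_cohort <- function(x, gap_s = 60, min_rows = 30) {
  if (is.character(x)) x <- read_cohort_csv(x)
  if (!inherits(x, "raw_cohort")) abort("`x` must be a `raw_cohort` or a directory path")

  participants <- x$participants
  sensors <- c("gps", "accel", "gyro")
  trips_out <- list()
  manifest <- list()
  exclusions <- list()
  mismatch_rows <- list()

  for (pid in unique(x$trips$participant_id)) {
    ptrips <- x$trips[x$trips$participant_id == pid, ]
    label <- participants$label[match(pid, participants$participant_id)]

    # concatenate each sensor's (possibly malfunction-affected) recordings
    # and re-segment from timestamps alone
    streams <- lapply(setNames(sensors, sensors), function(s) {
      parts <- ptrips[[s]][!vapply(ptrips[[s]], is.null, logical(1))]
      if (length(parts) == 0) return(NULL)
      df <- bind_rows(parts)
      df[order(df$time), ]
    })
    segs <- lapply(streams, function(df) {
      if (is.null(df)) {
        tibble(trip = integer(), start = integer(), end = integer())
      } else {
        segment_trips(df$time, gap_s = gap_s)
      }
    })
    counts <- vapply(segs, nrow, integer(1))
    mm <- check_mismatch(counts)
    mm$participant_id <- pid
    mismatch_rows[[length(mismatch_rows) + 1]] <- mm

    gps_segs <- segs$gps
    for (k in seq_len(nrow(gps_segs))) {
      gseg <- streams$gps[gps_segs$start[k]:gps_segs$end[k], ]
      span <- range(gseg$time)

      # match inertial segments by timestamp overlap with the GPS trip
      pick_overlap <- function(s) {
        sg <- segs[[s]]
        if (nrow(sg) == 0) return(NULL)
        t0 <- streams[[s]]$time[sg$start]
        t1 <- streams[[s]]$time[sg$end]
        ov <- pmin(t1, span[2]) - pmax(t0, span[1])
        j <- which.max(ov)
        if (length(j) == 0 || ov[j] <= 0) return(NULL)
        streams[[s]][sg$start[j]:sg$end[j], ]
      }
      aseg <- pick_overlap("accel")
      yseg <- pick_overlap("gyro")
      if (is.null(aseg) || is.null(yseg)) {
        exclusions[[length(exclusions) + 1]] <-
          tibble(participant_id = pid, trip_id = k, reason = "mismatch")
        next
      }

      rec <- synchronize(list(
        participant_id = pid, trip_id = k,
        gps = gseg, accel = aseg, gyro = yseg
      ))
      if ("incomplete" %in% rec$flags) {
        exclusions[[length(exclusions) + 1]] <-
          tibble(participant_id = pid, trip_id = k, reason = "incomplete")
        next
      }
      if (nrow(rec$merged_1hz) < min_rows) {
        exclusions[[length(exclusions) + 1]] <-
          tibble(participant_id = pid, trip_id = k, reason = "too_short")
        next
      }

      # attach generator ground truth (if present) by timestamp overlap
      src <- which(vapply(ptrips$gps, function(g) {
        !is.null(g) && g$time[1] <= span[2] && g$time[nrow(g)] >= span[1]
      }, logical(1)))
      rec$label <- label
      rec$impaired <- if (length(src)) any(ptrips$impaired[src]) else NA
      rec$corner_times <- if (length(src) == 1) ptrips$corner_times[[src]] else numeric()
      rec$start_time <- span[1]
      class(rec) <- "trip_record"

      trips_out[[length(trips_out) + 1]] <- rec
      manifest[[length(manifest) + 1]] <- tibble(
        participant_id = pid, trip_id = k, n_rows = nrow(rec$merged_1hz),
        label = label, impaired = rec$impaired,
        flags = paste(rec$flags, collapse = ";")
      )
    }
  }

  empty_manifest <- tibble(
    participant_id = character(), trip_id = integer(), n_rows = integer(),
    label = character(), impaired = logical(), flags = character()
  )
  structure(
    list(
      trips = trips_out,
      manifest = if (length(manifest)) bind_rows(manifest) else empty_manifest,
      exclusions = if (length(exclusions)) bind_rows(exclusions) else
        tibble(participant_id = character(), trip_id = integer(), reason = character()),
      mismatch = if (length(mismatch_rows)) bind_rows(mismatch_rows) else
        tibble(gps = integer(), accel = integer(), gyro = integer(),
               mismatch = logical(), participant_id = character()),
      participants = participants
    ),
    class = "cleaned_cohort"
  )
}

#' @export
print.cleaned_cohort <- function(x, ...) {
  cat(sprintf(
    "<cleaned_cohort> %d retained trips from %d participants; %d excluded\n",
    length(x$trips), length(unique(x$manifest$participant_id)), nrow(x$exclusions)
  ))
  invisible(x)
}
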