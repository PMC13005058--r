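# CSV layout: root/participant_<id>/<sensor>/trip_<k>.csv, one file per
# sensor per trip, with ISO-8601 timestamps (microsecond precision, UTC) and
# one column per modality channel. `participants.csv` and `ground_truth.csv`
# at the root carry the label table and the generator's per-trip ground truth
# so that export -> ingest -> export round-trips the whole tree.

format_iso_us <- function(t) {
  us <- round(t * 1e6)
  secs <- us %/% 1e6
  frac <- us %% 1e6
  base <- format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%S")
  sprintf("%s.%06dZ", base, frac)
}

parse_iso_us <- function(s) {
  base <- as.numeric(as.POSIXct(substr(s, 1, 19), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  frac <- as.numeric(substr(s, 21, 26)) / 1e6
  base + frac
}

#' Export a raw cohort to a per-participant/per-sensor CSV tree
#'
#' Writes the directory layout `root/participant_<id>/<sensor>/trip_<k>.csv`
#' (sensors `gps`, `accel`, `gyro`), plus `participants.csv` and
#' `ground_truth.csv` at the root. Timestamps are ISO-8601 UTC with
#' microsecond precision; the tree round-trips losslessly through
#' [read_cohort_csv()].
#'
#' @param cohort A `raw_cohort`.
#' @param root Writable directory (created if absent).
#' @return `root`, invisibly.
#' @export
export_cohort_csv <- function(cohort, root) {
  if (!inherits(cohort, "raw_cohort")) abort("`cohort` must be a `raw_cohort`")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) abort(sprintf("cannot create export directory: %s", root))

  readr::write_csv(cohort$participants, file.path(root, "participants.csv"))
  gt <- cohort$trips %>%
    select(all_of(c("participant_id", "trip_id", "impaired"))) %>%
    mutate(corner_times = vapply(
      cohort$trips$corner_times,
      function(ct) paste(sprintf("%.6f", ct), collapse = ";"),
      character(1)
    ))
  readr::write_csv(gt, file.path(root, "ground_truth.csv"))

  for (i in seq_len(nrow(cohort$trips))) {
    pid <- cohort$trips$participant_id[i]
    k <- cohort$trips$trip_id[i]
    for (s in c("gps", "accel", "gyro")) {
      stream <- cohort$trips[[s]][[i]]
      if (is.null(stream)) next
      dir <- file.path(root, paste0("participant_", pid), s)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out <- stream
      out$time <- format_iso_us(out$time)
      names(out)[names(out) == "time"] <- "timestamp"
      # fixed-precision channel values (nano-scale loss) so that
      # export -> ingest -> export is byte-identical
      for (ch in setdiff(names(out), "timestamp")) {
        out[[ch]] <- ifelse(is.na(out[[ch]]), NA, sprintf("%.9f", out[[ch]]))
      }
      path <- file.path(dir, sprintf("trip_%d.csv", k))
      tryCatch(
        readr::write_csv(out, path, na = ""),
        error = function(e) abort(sprintf("failed to write %s: %s", path, conditionMessage(e)))
      )
    }
  }
  invisible(root)
}

#' Read a cohort CSV tree back into a raw cohort
#'
#' Inverse of [export_cohort_csv()]. Streams dropped by sensor malfunctions
#' (missing files) come back as `NULL` entries, exactly as
#' [inject_malfunctions()] leaves them in memory.
#'
#' @param root Directory previously written by [export_cohort_csv()] (or any
#'   tree following the same layout).
#' @return A `raw_cohort` (with `config = NULL` when the tree carries none).
#' @export
read_cohort_csv <- function(root) {
  if (!dir.exists(root)) abort(sprintf("cohort directory not found: %s", root))
  ppath <- file.path(root, "participants.csv")
  participants <- if (file.exists(ppath)) {
    readr::read_csv(ppath, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble(participant_id = character(), age = integer(), sex = character(), label = character())
  }
  gtpath <- file.path(root, "ground_truth.csv")
  gt <- if (file.exists(gtpath)) {
    readr::read_csv(gtpath, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(corner_times = readr::col_character()))
  } else {
    NULL
  }

  pdirs <- list.dirs(root, recursive = FALSE)
  pdirs <- pdirs[grepl("participant_", basename(pdirs))]
  rows <- list()
  for (pd in pdirs) {
    pid <- sub("^participant_", "", basename(pd))
    trip_ids <- integer()
    for (s in c("gps", "accel", "gyro")) {
      fs <- list.files(file.path(pd, s), pattern = "^trip_\\d+\\.csv$")
      trip_ids <- union(trip_ids, as.integer(sub("^trip_(\\d+)\\.csv$", "\\1", fs)))
    }
    for (k in sort(trip_ids)) {
      streams <- lapply(c(gps = "gps", accel = "accel", gyro = "gyro"), function(s) {
        path <- file.path(pd, s, sprintf("trip_%d.csv", k))
        if (!file.exists(path)) return(NULL)
        df <- tryCatch(
          readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(timestamp = readr::col_character())),
          error = function(e) abort(sprintf("failed to read %s: %s", path, conditionMessage(e)))
        )
        df$timestamp <- parse_iso_us(df$timestamp)
        names(df)[names(df) == "timestamp"] <- "time"
        df
      })
      impaired <- FALSE
      corners <- numeric()
      if (!is.null(gt)) {
        hit <- gt$participant_id == pid & gt$trip_id == k
        if (any(hit)) {
          impaired <- gt$impaired[hit][1]
          ct <- gt$corner_times[hit][1]
          if (!is.na(ct) && nzchar(ct)) corners <- as.numeric(strsplit(ct, ";")[[1]])
        }
      }
      rows[[length(rows) + 1]] <- tibble(
        participant_id = pid, trip_id = k, impaired = impaired,
        gps = list(streams$gps), accel = list(streams$accel), gyro = list(streams$gyro),
        corner_times = list(corners)
      )
    }
  }
  trips <- if (length(rows)) bind_rows(rows) else tibble(
    participant_id = character(), trip_id = integer(), impaired = logical(),
    gps = list(), accel = list(), gyro = list(), corner_times = list()
  )
  structure(
    list(participants = participants, trips = trips, config = NULL),
    class = "raw_cohort"
  )
}
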