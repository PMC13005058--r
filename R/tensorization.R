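# Fixed-length resampling and assembly of the N x C x L series tensors for
# the four input modes: full trips (C = 10, L1 = 1200), turn windows
# (C = 10, L = 31), per-trip concatenated turns, channel-fused early-fusion
# input (C = 20) and the aligned pair used by dual-encoder late fusion.

#' Linearly resample a multichannel series to a fixed length
#'
#' Per-channel linear interpolation over normalized time `[0, 1]`. The first
#' and last rows are preserved exactly, and `T == L` returns the input
#' unchanged.
#'
#' @param series A `T x C` numeric matrix (T >= 2).
#' @param L Target length.
#' @return An `L x C` matrix with the same column names.
#' @examples
#' interpolate_to_length(cbind(ramp = seq(0, 1, length.out = 10)), 25)[c(1, 25), ]
#' @export
interpolate_to_length <- function(series, L) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 2) abort("`series` must have at least 2 rows")
  stopifnot_scalar_num(L, "L", 2)
  if (n == L) return(series)
  x <- seq(0, 1, length.out = n)
  xout <- seq(0, 1, length.out = L)
  out <- apply(series, 2, function(col) approx(x, col, xout = xout)$y)
  dimnames(out) <- list(NULL, colnames(series))
  out
}

new_series_tensor <- function(data, labels, participant_ids, trip_ids, mode,
                              mask = NULL) {
  structure(
    list(
      data = data, labels = as.integer(labels),
      participant_ids = participant_ids, trip_ids = trip_ids,
      mode = mode, mask = mask
    ),
    class = "series_tensor"
  )
}

#' @export
print.series_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<series_tensor mode=%s> N=%d, C=%d, L=%d (%d MCI / %d healthy)\n",
    x$mode, d[1], d[2], d[3], sum(x$labels == 1), sum(x$labels == 0)
  ))
  invisible(x)
}

#' Tidy the sample roster of a series tensor
#'
#' @param x A `series_tensor`.
#' @param ... Unused.
#' @return A tibble with one row per tensor sample: `participant_id`,
#'   `trip_id`, `label` (0 healthy / 1 MCI) and, when present, the zero-turn
#'   `mask` flag.
#' @exportS3Method generics::tidy
tidy.series_tensor <- function(x, ...) {
  out <- tibble(
    participant_id = x$participant_ids, trip_id = x$trip_ids, label = x$labels
  )
  if (!is.null(x$mask)) out$mask <- x$mask
  out
}

label_of <- function(label_chr) as.integer(label_chr == "mci")

#' Assemble the full-trip tensor
#'
#' Builds each retained trip's 10-channel matrix, resamples it to length `L`
#' and stacks the results into an `N x 10 x L` array with aligned label and
#' participant vectors.
#'
#' @param cleaned A `cleaned_cohort` (or list of `trip_record`s).
#' @param L Standardized trip length in time steps (default 1200).
#' @return A `series_tensor` with `mode = "trip"`.
#' @export
build_trip_tensor <- function(cleaned, L = 1200) {
  trips <- if (inherits(cleaned, "cleaned_cohort")) cleaned$trips else cleaned
  n <- length(trips)
  data <- array(0, dim = c(n, 10L, L), dimnames = list(NULL, CHANNELS_10, NULL))
  for (i in seq_len(n)) {
    data[i, , ] <- t(interpolate_to_length(build_channel_set(trips[[i]]), L))
  }
  new_series_tensor(
    data,
    labels = vapply(trips, function(tr) label_of(tr$label), integer(1)),
    participant_ids = vapply(trips, `[[`, character(1), "participant_id"),
    trip_ids = vapply(trips, function(tr) as.integer(tr$trip_id), integer(1)),
    mode = "trip"
  )
}

#' Assemble the turn tensor
#'
#' Two granularities are supported: `"per_turn"` stacks each fixed-length
#' turn window as its own sample (`N_turns x 10 x 31` at the defaults);
#' `"per_trip_concat"` concatenates each trip's turn windows in temporal
#' order and resamples the concatenation to length `L`, giving one sample
#' per trip aligned with the trip tensor. Trips without any detected turn
#' are zero-padded and flagged in `mask` (policy `"zero_pad"`, default) or
#' dropped (policy `"exclude"`).
#'
#' @param turns Result of [extract_turns()] (list with `segments`).
#' @param cleaned The `cleaned_cohort` the turns came from; required for
#'   `"per_trip_concat"` so that zero-turn trips stay aligned.
#' @param granularity `"per_trip_concat"` (default) or `"per_turn"`.
#' @param L Target length for concatenated turns (default 1200; late-fusion
#'   branches conventionally use a shorter length such as 310).
#' @param zero_turn Zero-turn-trip policy, `"zero_pad"` or `"exclude"`.
#' @return A `series_tensor` with `mode = "turn"`.
#' @export
build_turn_tensor <- function(turns, cleaned = NULL,
                              granularity = c("per_trip_concat", "per_turn"),
                              L = 1200,
                              zero_turn = c("zero_pad", "exclude")) {
  granularity <- match.arg(granularity)
  zero_turn <- match.arg(zero_turn)
  segments <- turns$segments

  if (granularity == "per_turn") {
    n <- length(segments)
    win_len <- if (n) nrow(segments[[1]]$window) else 31L
    data <- array(0, dim = c(n, 10L, win_len), dimnames = list(NULL, CHANNELS_10, NULL))
    labels <- integer(n); pids <- character(n); tids <- integer(n)
    lab_map <- if (!is.null(cleaned)) {
      setNames(cleaned$participants$label, cleaned$participants$participant_id)
    } else NULL
    for (i in seq_len(n)) {
      seg <- segments[[i]]
      data[i, , ] <- t(seg$window)
      pids[i] <- seg$participant_id
      tids[i] <- as.integer(seg$trip_id)
      labels[i] <- if (!is.null(lab_map)) label_of(lab_map[[seg$participant_id]]) else NA_integer_
    }
    return(new_series_tensor(data, labels, pids, tids, mode = "turn"))
  }

  if (is.null(cleaned)) abort("`cleaned` is required for per_trip_concat granularity")
  trips <- cleaned$trips
  keys <- vapply(segments, function(s) paste(s$participant_id, s$trip_id), character(1))
  keep <- logical(length(trips))
  rows <- vector("list", length(trips))
  mask <- logical(length(trips))
  for (i in seq_along(trips)) {
    tr <- trips[[i]]
    segs_i <- segments[keys == paste(tr$participant_id, tr$trip_id)]
    if (length(segs_i) == 0) {
      if (zero_turn == "exclude") next
      rows[[i]] <- matrix(0, L, 10L, dimnames = list(NULL, CHANNELS_10))
      mask[i] <- TRUE
      keep[i] <- TRUE
    } else {
      segs_i <- segs_i[order(vapply(segs_i, `[[`, integer(1), "peak_index"))]
      concat <- do.call(rbind, lapply(segs_i, `[[`, "window"))
      rows[[i]] <- interpolate_to_length(concat, L)
      keep[i] <- TRUE
    }
  }
  idx <- which(keep)
  data <- array(0, dim = c(length(idx), 10L, L), dimnames = list(NULL, CHANNELS_10, NULL))
  for (j in seq_along(idx)) data[j, , ] <- t(rows[[idx[j]]])
  new_series_tensor(
    data,
    labels = vapply(trips[idx], function(tr) label_of(tr$label), integer(1)),
    participant_ids = vapply(trips[idx], `[[`, character(1), "participant_id"),
    trip_ids = vapply(trips[idx], function(tr) as.integer(tr$trip_id), integer(1)),
    mode = "turn", mask = mask[idx]
  )
}

#' Fuse trip and concatenated-turn tensors along the channel axis
#'
#' Early (feature-level) fusion: channels 1-10 are the trip channels,
#' channels 11-20 the turn channels, for samples aligned by
#' (participant, trip).
#'
#' @param trip_tensor `series_tensor` in trip mode.
#' @param turn_tensor `series_tensor` in per-trip-concatenated turn mode with
#'   the same sample length.
#' @return A `series_tensor` with `mode = "early_fusion"` (`N x 20 x L`).
#' @export
build_fused_tensor <- function(trip_tensor, turn_tensor) {
  d1 <- dim(trip_tensor$data); d2 <- dim(turn_tensor$data)
  if (d1[1] != d2[1] || d1[3] != d2[3]) {
    abort(sprintf(
      "misaligned tensors: trip %d x %d x %d vs turn %d x %d x %d",
      d1[1], d1[2], d1[3], d2[1], d2[2], d2[3]
    ))
  }
  key1 <- paste(trip_tensor$participant_ids, trip_tensor$trip_ids)
  key2 <- paste(turn_tensor$participant_ids, turn_tensor$trip_ids)
  bad <- which(key1 != key2)
  if (length(bad)) {
    abort(sprintf("row %d misaligned: trip `%s` vs turn `%s`", bad[1], key1[bad[1]], key2[bad[1]]))
  }
  data <- array(0, dim = c(d1[1], 20L, d1[3]),
                dimnames = list(NULL, c(paste0("Trip_", CHANNELS_10), paste0("Turn_", CHANNELS_10)), NULL))
  if (d1[1] > 0) {
    data[, 1:10, ] <- trip_tensor$data
    data[, 11:20, ] <- turn_tensor$data
  }
  new_series_tensor(
    data, trip_tensor$labels, trip_tensor$participant_ids, trip_tensor$trip_ids,
    mode = "early_fusion", mask = turn_tensor$mask
  )
}

#' Pair trip and turn tensors for dual-encoder late fusion
#'
#' @param trip_tensor `series_tensor` in trip mode (length `L1`).
#' @param turn_tensor Aligned `series_tensor` of per-trip concatenated turns
#'   (length `L2`, conventionally different from `L1`).
#' @return An object of class `series_tensor_pair` carrying both tensors with
#'   shared labels.
#' @export
build_pair_tensor <- function(trip_tensor, turn_tensor) {
  if (dim(trip_tensor$data)[1] != dim(turn_tensor$data)[1]) {
    abort("misaligned tensors: different sample counts")
  }
  key1 <- paste(trip_tensor$participant_ids, trip_tensor$trip_ids)
  key2 <- paste(turn_tensor$participant_ids, turn_tensor$trip_ids)
  bad <- which(key1 != key2)
  if (length(bad)) {
    abort(sprintf("row %d misaligned: trip `%s` vs turn `%s`", bad[1], key1[bad[1]], key2[bad[1]]))
  }
  structure(
    list(
      trip = trip_tensor, turn = turn_tensor,
      labels = trip_tensor$labels,
      participant_ids = trip_tensor$participant_ids,
      trip_ids = trip_tensor$trip_ids,
      mode = "late_fusion_pair"
    ),
    class = "series_tensor_pair"
  )
}
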