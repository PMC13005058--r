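# The 10-channel kinematic feature set and the 14-feature static baseline.
# Channel order is fixed: Speed, Acc_X/Y/Z, Gyro_X/Y/Z, then the three
# derived angular accelerations Gyro_X/Y/Z_Acc obtained as temporal gradients
# of the gyroscope channels on the 1 Hz merged grid.

#' Angular acceleration from an angular-velocity series
#'
#' Temporal gradient of a gyroscope channel: second-order central differences
#' on interior points, first-order one-sided differences at the endpoints, so
#' the output has the same length as the input. Exact for linear inputs.
#'
#' @param x Numeric angular-velocity series (rad/s), length >= 2.
#' @param dt Sampling interval in seconds (default 1, the merged grid).
#' @return Numeric series of angular accelerations (rad/s^2), same length.
#' @examples
#' angular_acceleration(c(0, 1, 2, 3)) # constant 1 everywhere
#' @export
angular_acceleration <- function(x, dt = 1) {
  n <- length(x)
  if (n < 2) abort("`x` must have at least 2 samples")
  stopifnot_scalar_num(dt, "dt", 1e-12)
  if (n == 2) return(c(x[2] - x[1], x[2] - x[1]) / dt)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
}

#' Build the ordered 10-channel matrix of a trip
#'
#' @param trip A `trip_record` with `merged_1hz`.
#' @param derive_at Where to take the gyroscope temporal gradient:
#'   `"merged"` (default) differentiates the 1 Hz merged channels;
#'   `"raw"` differentiates the native-rate gyroscope stream first and then
#'   block-averages the result onto the merged grid (requires the raw
#'   `gyro` stream on the record).
#' @return An `S x 10` numeric matrix with columns `Speed`, `Acc_X`, `Acc_Y`,
#'   `Acc_Z`, `Gyro_X`, `Gyro_Y`, `Gyro_Z`, `Gyro_X_Acc`, `Gyro_Y_Acc`,
#'   `Gyro_Z_Acc` (fixed order).
#' @export
build_channel_set <- function(trip, derive_at = c("merged", "raw")) {
  derive_at <- match.arg(derive_at)
  m <- trip$merged_1hz
  if (is.null(m)) abort("trip has no merged 1 Hz table; run synchronize() first")
  if (derive_at == "merged") {
    derived <- cbind(
      Gyro_X_Acc = angular_acceleration(m$gyro_x, dt = 1),
      Gyro_Y_Acc = angular_acceleration(m$gyro_y, dt = 1),
      Gyro_Z_Acc = angular_acceleration(m$gyro_z, dt = 1)
    )
  } else {
    g <- trip$gyro
    if (is.null(g)) abort("raw gyroscope stream required for derive_at = \"raw\"")
    dt <- stats::median(diff(g$time))
    grp <- match(floor(g$time), floor(m$time))
    keep <- !is.na(grp)
    derived <- matrix(NA_real_, nrow(m), 3,
                      dimnames = list(NULL, c("Gyro_X_Acc", "Gyro_Y_Acc", "Gyro_Z_Acc")))
    for (j in seq_along(c("gyro_x", "gyro_y", "gyro_z"))) {
      ch <- c("gyro_x", "gyro_y", "gyro_z")[j]
      acc <- angular_acceleration(g[[ch]], dt = dt)[keep]
      sums <- rowsum(acc, grp[keep], reorder = FALSE)
      idx <- as.integer(rownames(sums))
      derived[idx, j] <- sums[, 1] / tabulate(grp[keep], nbins = nrow(m))[idx]
    }
    if (anyNA(derived)) {
      # seconds without raw coverage fall back to the merged-grid gradient
      fallback <- cbind(
        angular_acceleration(m$gyro_x, dt = 1),
        angular_acceleration(m$gyro_y, dt = 1),
        angular_acceleration(m$gyro_z, dt = 1)
      )
      derived[is.na(derived)] <- fallback[is.na(derived)]
    }
  }
  out <- cbind(
    Speed = m$speed,
    Acc_X = m$acc_x, Acc_Y = m$acc_y, Acc_Z = m$acc_z,
    Gyro_X = m$gyro_x, Gyro_Y = m$gyro_y, Gyro_Z = m$gyro_z,
    derived
  )
  stopifnot(identical(colnames(out), CHANNELS_10))
  out
}

#' Static summary features of a trip (nontemporal baseline)
#'
#' Mean and population standard deviation of the seven raw sensor channels
#' (accelerometer X/Y/Z, gyroscope X/Y/Z, speed), giving the 14-feature
#' vector used by the random-forest reference baseline.
#'
#' @param trip A `trip_record` with `merged_1hz` (at least 2 rows).
#' @return A 1-row tibble with 14 columns: `mean_*` then `sd_*` in the fixed
#'   channel order.
#' @export
static_features <- function(trip) {
  m <- trip$merged_1hz
  if (is.null(m)) abort("trip has no merged 1 Hz table; run synchronize() first")
  if (nrow(m) < 2) abort("at least 2 rows are needed for the SD features")
  chans <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z", "speed")
  means <- vapply(chans, function(ch) mean(m[[ch]]), numeric(1))
  sds <- vapply(chans, function(ch) pop_sd(m[[ch]]), numeric(1))
  out <- c(setNames(means, paste0("mean_", chans)), setNames(sds, paste0("sd_", chans)))
  as_tibble(as.list(out))
}
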