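# internal helpers shared across modules

# ordered channel names of the 10-channel kinematic feature set
CHANNELS_10 <- c(
  "Speed", "Acc_X", "Acc_Y", "Acc_Z",
  "Gyro_X", "Gyro_Y", "Gyro_Z",
  "Gyro_X_Acc", "Gyro_Y_Acc", "Gyro_Z_Acc"
)

# raw sensor channels as stored on the merged 1 Hz grid
MERGED_SENSOR_COLS <- c(
  "speed", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z"
)

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# wrap an angle (or vector of angles) into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# population (ddof = 0) standard deviation
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# run a draw under a private RNG stream without touching the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
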