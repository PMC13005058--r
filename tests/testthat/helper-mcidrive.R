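# shared fixtures, all generated in code

# small cohort used across module tests
tiny_cohort_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(
      n_healthy = 2, n_mci = 2, trips_per_participant = c(2, 3),
      trip_duration_s = c(100, 180), turn_count_per_trip = c(1, 3),
      seed = seed
    ),
    list(...)
  )
  do.call(cohort_config, args)
}

# hand-built trip record with known streams (n GPS seconds, 24 Hz IMU)
toy_trip_record <- function(n_sec = 40, imu_rate = 24, accel_value = NULL) {
  t0 <- 1e9
  imu_t <- t0 + (seq_len(n_sec * imu_rate) - 1) / imu_rate
  acc <- accel_value %||% stats::rnorm(length(imu_t))
  list(
    participant_id = "T01", trip_id = 1L,
    gps = tibble::tibble(
      time = t0 + (seq_len(n_sec) - 1),
      lat = 33.4 + cumsum(rep(1e-5, n_sec)),
      lon = -111.9 + cumsum(rep(1e-5, n_sec)),
      speed = rep(10, n_sec)
    ),
    accel = tibble::tibble(
      time = imu_t, acc_x = acc, acc_y = stats::rnorm(length(imu_t)),
      acc_z = stats::rnorm(length(imu_t))
    ),
    gyro = tibble::tibble(
      time = imu_t, gyro_x = stats::rnorm(length(imu_t)),
      gyro_y = stats::rnorm(length(imu_t)), gyro_z = stats::rnorm(length(imu_t))
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic planar path with one corner at a given sample (constant speed)
corner_path <- function(n = 101, corner_at = 50, angle = pi / 2) {
  step <- 0.01 # km per 1 Hz sample (10 m/s)
  headings <- c(rep(0, corner_at), rep(angle, n - corner_at - 1))
  x <- c(0, cumsum(step * cos(headings)))
  y <- c(0, cumsum(step * sin(headings)))
  cbind(x_km = x, y_km = y)
}

# brute-force turn oracle: scan every sample's successive-heading change and
# return local maxima above the threshold, one per cluster
oracle_corners <- function(xy, thr = 0.174533, cluster_gap = 5) {
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  ang <- atan2(dy, dx)
  dang <- abs(mcidrive:::wrap_angle(diff(ang)))
  cand <- which(dang > thr) + 1L
  if (length(cand) == 0) return(integer())
  runs <- split(cand, cumsum(c(1L, as.integer(diff(cand) > cluster_gap))))
  vapply(runs, function(run) run[which.max(dang[run - 1L])], integer(1))
}

# linearly separable toy tensor: class 1 has a shifted first channel
toy_tensor <- function(n = 64, C = 3, L = 40, shift = 2, seed = 5) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  data <- array(stats::rnorm(n * C * L), c(n, C, L))
  data[y == 1, 1, ] <- data[y == 1, 1, ] + shift
  mcidrive:::new_series_tensor(
    data, y, sprintf("P%02d", seq_len(n)), seq_len(n), "trip"
  )
}

toy_spec <- function(family, C = 3, L = 40, ...) {
  spec <- model_spec(family, in_channels = 10, seq_len = L, ...)
  spec$in_channels <- rep(as.integer(C), length(spec$in_channels))
  spec
}

# finite-difference gradient check on a handful of entries per parameter
grad_check <- function(spec, C = 3, L = 10, B = 4, eps = 1e-5, n_probe = 3) {
  set.seed(42)
  model <- build_model(spec, seed = 1)
  y <- rep(0:1, length.out = B)
  dual <- spec$dual
  xin <- if (!dual) {
    mcidrive:::seq_attr(matrix(stats::rnorm(C * B * L), C), L)
  } else {
    list(
      x1 = mcidrive:::seq_attr(matrix(stats::rnorm(C * B * L), C), L),
      x2 = mcidrive:::seq_attr(matrix(stats::rnorm(C * B * L), C), L)
    )
  }
  loss_fn <- function() {
    logits <- mcidrive:::model_forward(model, xin, training = TRUE)
    mcidrive:::softmax_xent(logits, y, c(1, 1.5))$loss
  }
  layers <- model$param_layers
  mcidrive:::zero_grads(layers)
  out <- mcidrive:::softmax_xent(
    mcidrive:::model_forward(model, xin, training = TRUE), y, c(1, 1.5)
  )
  mcidrive:::model_backward(model, out$dlogits)
  worst <- 0
  for (l in layers) {
    for (nm in names(l$par)) {
      p <- l$par[[nm]]
      for (j in sample(seq_along(p), min(n_probe, length(p)))) {
        orig <- p[j]
        l$par[[nm]][j] <- orig + eps
        lp <- loss_fn()
        l$par[[nm]][j] <- orig - eps
        lm <- loss_fn()
        l$par[[nm]][j] <- orig
        worst <- max(worst, abs((lp - lm) / (2 * eps) - l$grad[[nm]][j]))
      }
    }
  }
  worst
}
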