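test_that("specs validate family/attention combinations", {
  expect_s3_class(model_spec("tiny_fcn"), "model_spec")
  expect_error(model_spec("tiny_fcn", attention = "single"), "recurrent")
  expect_error(model_spec("gru", attention = "self"), "TCN")
  expect_error(model_spec("cnn1d", in_channels = 7), "channels")
  expect_error(model_spec("nope"), "arg")
  dual <- model_spec("gru", dual = TRUE, fusion = "gated", seq_len = c(100, 30))
  expect_length(dual$in_channels, 2)
})

test_that("outputs satisfy the probability contract", {
  tensor <- toy_tensor(n = 8, C = 3, L = 30)
  model <- build_model(toy_spec("tiny_fcn", L = 30), seed = 2)
  p <- predict_proba(model, tensor)
  expect_equal(dim(p), c(8, 2))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))

  # duplicated inputs give duplicated outputs; batch order is irrelevant
  dup <- tensor
  dup$data[2, , ] <- dup$data[1, , ]
  pd <- predict_proba(model, dup)
  expect_equal(pd[1, ], pd[2, ])
  perm <- sample(8)
  shuf <- tensor
  shuf$data <- tensor$data[perm, , , drop = FALSE]
  expect_equal(predict_proba(model, shuf), p[perm, ], tolerance = 1e-12)

  # zero logits split the softmax evenly
  expect_equal(mcidrive:::softmax_cols(matrix(0, 2, 3)), matrix(0.5, 2, 3))
})

test_that("initialization is fully determined by spec and seed", {
  for (family in c("tiny_fcn", "gru", "tcn")) {
    spec <- toy_spec(family, L = 20)
    a <- build_model(spec, seed = 11)
    b <- build_model(spec, seed = 11)
    c <- build_model(spec, seed = 12)
    expect_identical(
      mcidrive:::param_checksum(a$param_layers),
      mcidrive:::param_checksum(b$param_layers)
    )
    expect_false(
      mcidrive:::param_checksum(a$param_layers) == mcidrive:::param_checksum(c$param_layers)
    )
    expect_identical(
      mcidrive:::n_parameters(a$param_layers), mcidrive:::n_parameters(c$param_layers)
    )
  }
  # dual concat head width is the sum of the branch latent dims
  d <- build_model(model_spec("tiny_fcn", dual = TRUE, fusion = "concat",
                              seq_len = c(40, 20)), seed = 1)
  expect_equal(d$head_in, sum(d$latent_dim))
})

test_that("analytic gradients agree with finite differences in every family", {
  cases <- list(
    toy_spec("tiny_fcn"),
    toy_spec("inception_time_small", L = 24),
    toy_spec("resnet_tsc"),
    toy_spec("gru", attention = "single"),
    toy_spec("gru", attention = "multihead"),
    toy_spec("lstm"),
    toy_spec("tcn", attention = "self"),
    toy_spec("tiny_fcn", dual = TRUE, fusion = "gated"),
    toy_spec("gru", dual = TRUE, fusion = "concat")
  )
  for (spec in cases) {
    L <- max(spec$seq_len[1], 10)
    expect_lt(grad_check(spec, C = 3, L = L, B = 3), 1e-6)
  }
})

test_that("every family fits a linearly separable toy problem", {
  tensor <- toy_tensor(n = 64, C = 3, L = 40, shift = 2.5)
  for (family in mcidrive:::MODEL_FAMILIES) {
    model <- train_model(
      toy_spec(family, L = 40), tensor,
      train_config(epochs = 200, batch_size = 32, class_weights = FALSE, seed = 8),
      stop_loss = 0.1
    )
    final <- model$history$loss[nrow(model$history)]
    expect_lt(final, 0.1)
  }
})

test_that("a gate forced to the trip branch reproduces the single-view model", {
  set.seed(3)
  L1 <- 30; L2 <- 18
  dual <- build_model(
    model_spec("tiny_fcn", dual = TRUE, fusion = "gated",
               in_channels = c(10, 10), seq_len = c(L1, L2)),
    seed = 5
  )
  single <- build_model(model_spec("tiny_fcn", in_channels = 10, seq_len = L1), seed = 6)

  # copy the dual trip encoder and head into the single-view model
  enc_dual <- mcidrive:::collect_param_layers(dual$enc1)
  head_dual <- mcidrive:::collect_param_layers(dual$head)
  single_layers <- single$param_layers
  for (i in seq_along(enc_dual)) single_layers[[i]]$par <- enc_dual[[i]]$par
  single_layers[[length(single_layers)]]$par <- head_dual[[1]]$par

  # force the gate fully open toward the trip latent
  dual$gate$par$W[] <- 0
  dual$gate$par$b[] <- 50

  n <- 6
  trip_data <- array(stats::rnorm(n * 10 * L1), c(n, 10, L1))
  turn_data <- array(stats::rnorm(n * 10 * L2), c(n, 10, L2))
  labels <- rep(0:1, 3)
  pair <- build_pair_tensor(
    mcidrive:::new_series_tensor(trip_data, labels, sprintf("P%d", 1:n), 1:n, "trip"),
    mcidrive:::new_series_tensor(turn_data, labels, sprintf("P%d", 1:n), 1:n, "turn")
  )
  trip_only <- mcidrive:::new_series_tensor(trip_data, labels, sprintf("P%d", 1:n), 1:n, "trip")
  expect_equal(predict_proba(dual, pair), predict_proba(single, trip_only), tolerance = 1e-8)
})
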