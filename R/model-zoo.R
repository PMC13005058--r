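# Reference architectures for the three families used on driving time
# series: 1-D convolutional networks (plain CNN, fully convolutional TinyFCN,
# reduced Inception variants, a residual time-series-classification net),
# recurrent networks (GRU / LSTM, optionally with additive attention
# pooling), and temporal convolutional networks (dilated causal convolution
# stacks). Every variant ends in global pooling and a linear two-class head;
# dual variants run two weight-independent encoders whose latent vectors are
# merged by concatenation or a learned sigmoid gate.

MODEL_FAMILIES <- c(
  "cnn1d", "tiny_fcn", "inception_lite", "inception_time_small",
  "resnet_tsc", "gru", "lstm", "tcn", "tiny_tcn"
)

#' Specify a classifier architecture
#'
#' @param family One of `"cnn1d"`, `"tiny_fcn"`, `"inception_lite"`,
#'   `"inception_time_small"`, `"resnet_tsc"`, `"gru"`, `"lstm"`, `"tcn"`,
#'   `"tiny_tcn"`.
#' @param attention `"none"` (default); `"single"`/`"multihead"` (additive
#'   attention pooling, 1 or 4 score heads) for the recurrent families;
#'   `"self"` (learned-query dot-product pooling) for the TCN families.
#' @param dual If `TRUE`, build a dual-encoder late-fusion model: two
#'   weight-independent encoders of the chosen family, one per input branch.
#' @param fusion Latent merge for dual models: `"concat"` or `"gated"`
#'   (sigmoid gate `g` computed from both latents, output
#'   `g * z_trip + (1 - g) * z_turn`).
#' @param in_channels Input channels (10 for single-view/late-fusion inputs,
#'   20 for the early-fusion tensor). For dual models a length-2 vector.
#' @param seq_len Sequence length, or a length-2 vector `(L1, L2)` for dual
#'   models.
#' @param dropout Optional dropout rate applied before the linear head.
#' @param n_classes Number of classes (fixed at 2).
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("tiny_fcn", in_channels = 10, seq_len = 1200)
#' model_spec("tiny_fcn", dual = TRUE, fusion = "gated", seq_len = c(1200, 310))
#' @export
model_spec <- function(family,
                       attention = c("none", "single", "multihead", "self"),
                       dual = FALSE,
                       fusion = c("concat", "gated"),
                       in_channels = 10,
                       seq_len = 1200,
                       dropout = 0,
                       n_classes = 2) {
  family <- match.arg(family, MODEL_FAMILIES)
  attention <- match.arg(attention)
  fusion <- match.arg(fusion)
  if (n_classes != 2) abort("only binary classification is supported")
  rnn <- family %in% c("gru", "lstm")
  tcn <- family %in% c("tcn", "tiny_tcn")
  if (attention %in% c("single", "multihead") && !rnn) {
    abort(sprintf("attention `%s` is only available for recurrent families", attention))
  }
  if (attention == "self" && !tcn) {
    abort("attention `self` is only available for the TCN families")
  }
  if (!dual && !in_channels[1] %in% c(10, 20)) {
    abort("single models take 10 (single-view) or 20 (early fusion) input channels")
  }
  if (dual) {
    if (length(in_channels) == 1) in_channels <- rep(in_channels, 2)
    if (length(seq_len) == 1) seq_len <- rep(seq_len, 2)
  }
  structure(
    list(
      family = family, attention = attention, dual = dual,
      fusion = if (dual) fusion else NULL,
      in_channels = as.integer(in_channels), seq_len = as.integer(seq_len),
      dropout = dropout, n_classes = 2L
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %s%s%s | C=%s, L=%s%s\n",
    if (x$dual) "dual " else "", x$family,
    if (x$attention != "none") paste0(" + ", x$attention, " attention") else "",
    paste(x$in_channels, collapse = "/"), paste(x$seq_len, collapse = "/"),
    if (x$dual) paste0(" | fusion=", x$fusion) else ""
  ))
  invisible(x)
}

# encoder network of a family: sequence input -> latent vector (d x B);
# returns list(net, latent_dim)
build_encoder <- function(family, in_ch, attention = "none", hidden = 64L) {
  conv_bn_relu <- function(ci, co, k, dil = 1, causal = FALSE) {
    list(nn_conv1d(ci, co, k, dil, causal), nn_batchnorm(co), nn_relu())
  }
  switch(family,
    cnn1d = list(
      net = nn_seq(c(
        list(nn_conv1d(in_ch, 16, 7), nn_relu(), nn_conv1d(16, 32, 5), nn_relu()),
        list(nn_gap())
      )),
      latent_dim = 32L
    ),
    tiny_fcn = list(
      net = nn_seq(c(
        conv_bn_relu(in_ch, 32, 8), conv_bn_relu(32, 64, 5), conv_bn_relu(64, 32, 3),
        list(nn_gap())
      )),
      latent_dim = 32L
    ),
    inception_lite = {
      block <- function(ci) {
        list(
          nn_parallel_concat(list(
            nn_conv1d(ci, 8, 1), nn_conv1d(ci, 8, 3),
            nn_conv1d(ci, 8, 5), nn_conv1d(ci, 8, 9)
          )),
          nn_batchnorm(32), nn_relu()
        )
      }
      list(
        net = nn_seq(c(block(in_ch), block(32), list(nn_gap()))),
        latent_dim = 32L
      )
    },
    inception_time_small = {
      block <- function(ci) {
        list(
          nn_parallel_concat(list(
            nn_conv1d(ci, 8, 1), nn_conv1d(ci, 8, 3),
            nn_conv1d(ci, 8, 9), nn_conv1d(ci, 8, 19)
          )),
          nn_batchnorm(32), nn_relu()
        )
      }
      trunk <- nn_seq(c(block(in_ch), block(32), block(32)))
      shortcut <- nn_seq(list(nn_conv1d(in_ch, 32, 1), nn_batchnorm(32)))
      list(
        net = nn_seq(list(nn_add(list(trunk, shortcut)), nn_gap())),
        latent_dim = 32L
      )
    },
    resnet_tsc = {
      res_block <- function(ci, co) {
        main <- nn_seq(c(
          conv_bn_relu(ci, co, 8), conv_bn_relu(co, co, 5),
          list(nn_conv1d(co, co, 3), nn_batchnorm(co))
        ))
        short <- nn_seq(list(nn_conv1d(ci, co, 1), nn_batchnorm(co)))
        nn_add(list(main, short))
      }
      list(
        net = nn_seq(list(
          res_block(in_ch, 32), res_block(32, 64), res_block(64, 64), nn_gap()
        )),
        latent_dim = 64L
      )
    },
    gru = ,
    lstm = {
      rnn_ctor <- if (family == "gru") nn_gru else nn_lstm
      if (attention == "none") {
        list(
          net = nn_seq(list(rnn_ctor(in_ch, hidden, return_seq = FALSE))),
          latent_dim = hidden
        )
      } else {
        heads <- if (attention == "multihead") 4L else 1L
        list(
          net = nn_seq(list(
            rnn_ctor(in_ch, hidden, return_seq = TRUE),
            nn_attnpool(hidden, d_att = hidden, heads = heads)
          )),
          latent_dim = hidden * heads
        )
      }
    },
    tcn = ,
    tiny_tcn = {
      ch <- if (family == "tcn") 32L else 16L
      level <- function(ci, dil) {
        main <- nn_seq(list(
          nn_conv1d(ci, ch, 3, dilation = dil, causal = TRUE), nn_relu(),
          nn_conv1d(ch, ch, 3, dilation = dil, causal = TRUE)
        ))
        short <- if (ci == ch) nn_identity() else nn_conv1d(ci, ch, 1)
        nn_add(list(main, short))
      }
      pool <- if (attention == "self") nn_selfpool(ch) else nn_gap()
      list(
        net = nn_seq(list(
          level(in_ch, 1), level(ch, 2), level(ch, 4), level(ch, 8), pool
        )),
        latent_dim = ch
      )
    }
  )
}

#' Build a classifier from a model specification
#'
#' Parameter initialization is driven entirely by `seed`: two builds with the
#' same spec and seed have identical parameters.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `mcidrive_model` mapping a `series_tensor`
#'   (or `series_tensor_pair` for dual specs) to per-class scores.
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "model_spec")) abort("`spec` must be a `model_spec`")
  model <- with_seed(seed, {
    if (!spec$dual) {
      enc <- build_encoder(spec$family, spec$in_channels[1], spec$attention)
      head_in <- enc$latent_dim
      net <- nn_seq(c(
        list(enc$net),
        if (spec$dropout > 0) list(nn_dropout(spec$dropout)),
        list(nn_linear(head_in, 2L))
      ))
      list(kind = "single", net = net, latent_dim = enc$latent_dim)
    } else {
      enc1 <- build_encoder(spec$family, spec$in_channels[1], spec$attention)
      enc2 <- build_encoder(spec$family, spec$in_channels[2], spec$attention)
      d1 <- enc1$latent_dim; d2 <- enc2$latent_dim
      gate <- NULL
      if (spec$fusion == "gated") {
        if (d1 != d2) abort("gated fusion requires equal branch latent dims")
        gate <- nn_linear(d1 + d2, d1)
        head_in <- d1
      } else {
        head_in <- d1 + d2
      }
      head <- nn_seq(c(
        if (spec$dropout > 0) list(nn_dropout(spec$dropout)),
        list(nn_linear(head_in, 2L))
      ))
      list(
        kind = "dual", enc1 = enc1$net, enc2 = enc2$net, gate = gate,
        head = head, latent_dim = c(d1, d2), head_in = head_in,
        fuse = new.env(parent = emptyenv())
      )
    }
  })
  model$spec <- spec
  model$seed <- as.integer(seed)
  model$param_layers <- if (model$kind == "single") {
    collect_param_layers(model$net)
  } else {
    c(
      collect_param_layers(model$enc1), collect_param_layers(model$enc2),
      if (!is.null(model$gate)) list(model$gate), collect_param_layers(model$head)
    )
  }
  class(model) <- "mcidrive_model"
  model
}

#' @export
print.mcidrive_model <- function(x, ...) {
  cat(sprintf(
    "<mcidrive_model> %s%s | %d parameters%s\n",
    if (x$spec$dual) "dual " else "", x$spec$family,
    n_parameters(x$param_layers),
    if (!is.null(x$trained) && x$trained) " (trained)" else " (initialized)"
  ))
  invisible(x)
}

# convert tensor samples idx to the C x (B * L) batch layout
tensor_batch <- function(data, idx) {
  sub <- data[idx, , , drop = FALSE]
  d <- dim(sub)
  x <- aperm(sub, c(2, 3, 1))
  dim(x) <- c(d[2], d[3] * d[1])
  seq_attr(x, d[3])
}

model_forward <- function(model, x, training = FALSE) {
  if (model$kind == "single") {
    model$net$fwd(x, training)
  } else {
    z1 <- model$enc1$fwd(x$x1, training)
    z2 <- model$enc2$fwd(x$x2, training)
    if (is.null(model$gate)) {
      z <- rbind(z1, z2)
      model$fuse$cache <- NULL
    } else {
      s <- rbind(z1, z2)
      a <- model$gate$fwd(seq_attr(s, 1L), training)
      g <- 1 / (1 + exp(-a))
      z <- g * z1 + (1 - g) * z2
      model$fuse$cache <- list(g = g, z1 = z1, z2 = z2)
    }
    model$head$fwd(seq_attr(z, 1L), training)
  }
}

model_backward <- function(model, dlogits) {
  if (model$kind == "single") {
    model$net$bwd(dlogits)
    return(invisible(NULL))
  }
  dz <- model$head$bwd(dlogits)
  if (is.null(model$gate)) {
    n1 <- model$latent_dim[1]
    dz1 <- dz[seq_len(n1), , drop = FALSE]
    dz2 <- dz[(n1 + 1):nrow(dz), , drop = FALSE]
  } else {
    fc <- model$fuse$cache
    g <- fc$g
    dz1 <- dz * g
    dz2 <- dz * (1 - g)
    dgate <- dz * (fc$z1 - fc$z2)
    da <- dgate * g * (1 - g)
    ds <- model$gate$bwd(seq_attr(da, 1L))
    n1 <- model$latent_dim[1]
    dz1 <- dz1 + ds[seq_len(n1), , drop = FALSE]
    dz2 <- dz2 + ds[(n1 + 1):nrow(ds), , drop = FALSE]
  }
  model$enc1$bwd(seq_attr(dz1, 1L))
  model$enc2$bwd(seq_attr(dz2, 1L))
  invisible(NULL)
}

# assemble forward input(s) for sample indices of a tensor / tensor pair
model_input <- function(model, tensor, idx) {
  if (model$kind == "single") {
    tensor_batch(tensor$data, idx)
  } else {
    list(
      x1 = tensor_batch(tensor$trip$data, idx),
      x2 = tensor_batch(tensor$turn$data, idx)
    )
  }
}

tensor_n <- function(tensor) {
  if (inherits(tensor, "series_tensor_pair")) dim(tensor$trip$data)[1] else dim(tensor$data)[1]
}

check_tensor_spec <- function(model, tensor) {
  spec <- model$spec
  if (model$kind == "single") {
    if (inherits(tensor, "series_tensor_pair")) abort("single model expects one tensor")
    d <- dim(tensor$data)
    if (d[2] != spec$in_channels[1]) {
      abort(sprintf("tensor has %d channels but the spec expects %d", d[2], spec$in_channels[1]))
    }
  } else {
    if (!inherits(tensor, "series_tensor_pair")) abort("dual model expects a `series_tensor_pair`")
    d1 <- dim(tensor$trip$data); d2 <- dim(tensor$turn$data)
    if (d1[2] != spec$in_channels[1] || d2[2] != spec$in_channels[2]) {
      abort("tensor pair channels do not match the dual spec")
    }
  }
  invisible(TRUE)
}

#' Predict class probabilities
#'
#' Runs the model in evaluation mode (batch-norm running statistics, no
#' dropout), so predictions are deterministic.
#'
#' @param model A built (and usually trained) `mcidrive_model`.
#' @param tensor A `series_tensor` (or `series_tensor_pair` for dual models).
#' @param batch_size Evaluation batch size.
#' @return An `N x 2` matrix of probabilities (columns `healthy`, `mci`),
#'   rows summing to 1.
#' @export
predict_proba <- function(model, tensor, batch_size = 64L) {
  check_tensor_spec(model, tensor)
  n <- tensor_n(tensor)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("healthy", "mci")))
  for (start in seq(1L, max(n, 1L), by = batch_size)) {
    if (n == 0) break
    idx <- start:min(n, start + batch_size - 1L)
    logits <- model_forward(model, model_input(model, tensor, idx), training = FALSE)
    out[idx, ] <- t(softmax_cols(logits))
  }
  out
}
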