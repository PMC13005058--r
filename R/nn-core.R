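# Minimal neural-network kernel used by the model zoo: layers store their
# parameters and Adam state in closures, forward passes cache what backward
# needs, and all heavy lifting is batched dense matrix algebra (BLAS).
#
# Data layout convention: a batch of multivariate sequences is a C x (B * L)
# matrix whose column (b - 1) * L + t holds sample b at time t, with the
# per-sample length L carried in attr(x, "L"). Pooled latent representations
# are d x B matrices with attr "L" = 1. This keeps 1-D convolutions a single
# GEMM over the whole batch (im2col).

seq_attr <- function(x, L) {
  attr(x, "L") <- as.integer(L)
  x
}

new_nn_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$par <- list()
  e$grad <- list()
  class(e) <- "nn_layer"
  e
}

# ---- parameter bookkeeping ------------------------------------------------

collect_param_layers <- function(layer) {
  out <- list()
  if (length(layer$par)) out <- list(layer)
  for (slot in c("layers", "branches")) {
    if (!is.null(layer[[slot]])) {
      for (sub in layer[[slot]]) out <- c(out, collect_param_layers(sub))
    }
  }
  out
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, length, numeric(1))), numeric(1)))
}

param_checksum <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, function(p) sum(abs(p)), numeric(1))), numeric(1)))
}

zero_grads <- function(layers) {
  for (l in layers) {
    l$grad <- lapply(l$par, function(p) p * 0)
  }
  invisible(NULL)
}

# decoupled-weight-decay Adam update over all parameter layers
adamw_step <- function(layers, lr, weight_decay, step,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1c <- 1 - beta1^step
  b2c <- 1 - beta2^step
  for (l in layers) {
    if (is.null(l$opt)) {
      l$opt <- list(
        m = lapply(l$par, function(p) p * 0),
        v = lapply(l$par, function(p) p * 0)
      )
    }
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * g
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * g^2
      mhat <- l$opt$m[[nm]] / b1c
      vhat <- l$opt$v[[nm]] / b2c
      l$par[[nm]] <- l$par[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
        lr * weight_decay * l$par[[nm]]
    }
  }
  invisible(NULL)
}

# ---- elementary layers ----------------------------------------------------

nn_conv1d <- function(in_ch, out_ch, kernel, dilation = 1L, causal = FALSE) {
  l <- new_nn_layer("conv1d")
  l$in_ch <- in_ch; l$out_ch <- out_ch; l$kernel <- as.integer(kernel)
  l$dilation <- as.integer(dilation); l$causal <- causal
  l$par <- list(
    W = matrix(rnorm(out_ch * in_ch * kernel, 0, sqrt(2 / (in_ch * kernel))),
               out_ch, in_ch * kernel),
    b = numeric(out_ch)
  )
  span <- (l$kernel - 1L) * l$dilation
  l$pl <- if (causal) span else span %/% 2L
  l$pr <- span - l$pl

  l$fwd <- function(x, training = FALSE) {
    L <- attr(x, "L"); B <- ncol(x) / L
    Lp <- L + l$pl + l$pr
    main_idx <- rep((seq_len(B) - 1) * Lp, each = L) + l$pl + seq_len(L)
    xpad <- matrix(0, l$in_ch, B * Lp)
    xpad[, main_idx] <- x
    xcol <- matrix(0, l$in_ch * l$kernel, B * L)
    base <- rep((seq_len(B) - 1) * Lp, each = L) + seq_len(L)
    for (k in seq_len(l$kernel)) {
      rows <- ((k - 1) * l$in_ch + 1):(k * l$in_ch)
      xcol[rows, ] <- xpad[, base + (k - 1) * l$dilation, drop = FALSE]
    }
    l$cache <- list(xcol = xcol, L = L, B = B, Lp = Lp, base = base, main_idx = main_idx)
    seq_attr(l$par$W %*% xcol + l$par$b, L)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    l$grad$W <- l$grad$W + tcrossprod(dy, cc$xcol)
    l$grad$b <- l$grad$b + rowSums(dy)
    dxcol <- crossprod(l$par$W, dy)
    dxpad <- matrix(0, l$in_ch, cc$B * cc$Lp)
    for (k in seq_len(l$kernel)) {
      rows <- ((k - 1) * l$in_ch + 1):(k * l$in_ch)
      cols <- cc$base + (k - 1) * l$dilation
      dxpad[, cols] <- dxpad[, cols, drop = FALSE] + dxcol[rows, , drop = FALSE]
    }
    seq_attr(dxpad[, cc$main_idx, drop = FALSE], cc$L)
  }
  l
}

nn_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new_nn_layer("batchnorm")
  l$par <- list(gamma = rep(1, ch), beta = numeric(ch))
  l$run_mean <- numeric(ch)
  l$run_var <- rep(1, ch)
  l$eps <- eps; l$momentum <- momentum

  l$fwd <- function(x, training = FALSE) {
    if (training) {
      mu <- rowMeans(x)
      va <- rowMeans(x^2) - mu^2
      va <- pmax(va, 0)
      inv <- 1 / sqrt(va + l$eps)
      xhat <- (x - mu) * inv
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
      l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * va
      l$cache <- list(xhat = xhat, inv = inv, training = TRUE)
      seq_attr(l$par$gamma * xhat + l$par$beta, attr(x, "L"))
    } else {
      inv <- 1 / sqrt(l$run_var + l$eps)
      l$cache <- list(inv = inv, training = FALSE)
      seq_attr(l$par$gamma * ((x - l$run_mean) * inv) + l$par$beta, attr(x, "L"))
    }
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    if (!cc$training) {
      return(seq_attr(dy * (l$par$gamma * cc$inv), attr(dy, "L")))
    }
    m <- ncol(dy)
    dgamma <- rowSums(dy * cc$xhat)
    dbeta <- rowSums(dy)
    l$grad$gamma <- l$grad$gamma + dgamma
    l$grad$beta <- l$grad$beta + dbeta
    dx <- (l$par$gamma * cc$inv) * (dy - dbeta / m - cc$xhat * (dgamma / m))
    seq_attr(dx, attr(dy, "L"))
  }
  l
}

nn_relu <- function() {
  l <- new_nn_layer("relu")
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x > 0
    seq_attr(x * l$cache, attr(x, "L"))
  }
  l$bwd <- function(dy) seq_attr(dy * l$cache, attr(dy, "L"))
  l
}

nn_dropout <- function(rate) {
  l <- new_nn_layer("dropout")
  l$rate <- rate
  l$fwd <- function(x, training = FALSE) {
    if (!training || l$rate <= 0) {
      l$cache <- NULL
      return(x)
    }
    mask <- (matrix(runif(length(x)), nrow(x)) >= l$rate) / (1 - l$rate)
    l$cache <- mask
    seq_attr(x * mask, attr(x, "L"))
  }
  l$bwd <- function(dy) {
    if (is.null(l$cache)) return(dy)
    seq_attr(dy * l$cache, attr(dy, "L"))
  }
  l
}

# global average pooling over time: C x (B * L) -> C x B
nn_gap <- function() {
  l <- new_nn_layer("gap")
  l$fwd <- function(x, training = FALSE) {
    L <- attr(x, "L"); B <- ncol(x) / L
    gb <- rep(seq_len(B), each = L)
    l$cache <- list(L = L, B = B)
    seq_attr(t(rowsum(t(x), gb, reorder = FALSE)) / L, 1L)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    seq_attr(dy[, rep(seq_len(cc$B), each = cc$L), drop = FALSE] / cc$L, cc$L)
  }
  l
}

# take the final timestep: C x (B * L) -> C x B
nn_last_step <- function() {
  l <- new_nn_layer("last_step")
  l$fwd <- function(x, training = FALSE) {
    L <- attr(x, "L"); B <- ncol(x) / L
    l$cache <- list(L = L, B = B, d = nrow(x))
    seq_attr(x[, (seq_len(B)) * L, drop = FALSE], 1L)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    dx <- matrix(0, cc$d, cc$B * cc$L)
    dx[, seq_len(cc$B) * cc$L] <- dy
    seq_attr(dx, cc$L)
  }
  l
}

nn_linear <- function(d_in, d_out) {
  l <- new_nn_layer("linear")
  l$par <- list(
    W = matrix(rnorm(d_out * d_in, 0, sqrt(1 / d_in)), d_out, d_in),
    b = numeric(d_out)
  )
  l$fwd <- function(x, training = FALSE) {
    l$cache <- x
    seq_attr(l$par$W %*% x + l$par$b, attr(x, "L") %||% 1L)
  }
  l$bwd <- function(dy) {
    l$grad$W <- l$grad$W + tcrossprod(dy, l$cache)
    l$grad$b <- l$grad$b + rowSums(dy)
    seq_attr(crossprod(l$par$W, dy), attr(l$cache, "L") %||% 1L)
  }
  l
}

# column-wise softmax over the L rows of each sample
softmax_cols <- function(m) {
  m <- exp(m - rep(apply(m, 2, max), each = nrow(m)))
  m / rep(colSums(m), each = nrow(m))
}

# additive (Bahdanau-style) attention pooling over time, optionally with
# several independent score heads whose pooled vectors are concatenated:
# d x (B * L) -> (d * heads) x B
nn_attnpool <- function(d_in, d_att = 64L, heads = 1L) {
  l <- new_nn_layer("attnpool")
  l$heads <- as.integer(heads); l$d_in <- d_in; l$d_att <- d_att
  l$par <- list(
    W = matrix(rnorm(d_att * d_in, 0, sqrt(1 / d_in)), d_att, d_in),
    b = numeric(d_att),
    V = matrix(rnorm(heads * d_att, 0, sqrt(1 / d_att)), heads, d_att)
  )
  l$fwd <- function(x, training = FALSE) {
    L <- attr(x, "L"); B <- ncol(x) / L
    u <- tanh(l$par$W %*% x + l$par$b)
    S <- l$par$V %*% u # heads x (B*L)
    alphas <- vector("list", l$heads)
    out <- matrix(0, l$d_in * l$heads, B)
    for (h in seq_len(l$heads)) {
      a <- softmax_cols(matrix(S[h, ], L, B))
      alphas[[h]] <- a
      av <- as.vector(a)
      xw <- x * rep(av, each = l$d_in)
      pooled <- t(rowsum(t(xw), rep(seq_len(B), each = L), reorder = FALSE))
      out[((h - 1) * l$d_in + 1):(h * l$d_in), ] <- pooled
    }
    l$cache <- list(x = x, u = u, alphas = alphas, L = L, B = B)
    seq_attr(out, 1L)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    L <- cc$L; B <- cc$B; d <- l$d_in
    gb <- rep(seq_len(B), each = L)
    dS <- matrix(0, l$heads, B * L)
    dx <- matrix(0, d, B * L)
    for (h in seq_len(l$heads)) {
      dout <- dy[((h - 1) * d + 1):(h * d), , drop = FALSE]
      a <- cc$alphas[[h]]
      av <- as.vector(a)
      # dx from the weighted sum
      dx <- dx + dout[, gb, drop = FALSE] * rep(av, each = d)
      # dalpha[t, b] = sum_d x[d, (b,t)] * dout[d, b]
      dalpha <- matrix(colSums(cc$x * dout[, gb, drop = FALSE]), L, B)
      # softmax backward per column
      ds <- a * (dalpha - rep(colSums(a * dalpha), each = L))
      dS[h, ] <- as.vector(ds)
    }
    l$grad$V <- l$grad$V + tcrossprod(dS, cc$u)
    du <- crossprod(l$par$V, dS)
    da <- du * (1 - cc$u^2)
    l$grad$W <- l$grad$W + tcrossprod(da, cc$x)
    l$grad$b <- l$grad$b + rowSums(da)
    dx <- dx + crossprod(l$par$W, da)
    seq_attr(dx, L)
  }
  l
}

# dot-product attention pooling with a learned query: d x (B * L) -> d x B
nn_selfpool <- function(d_in) {
  l <- new_nn_layer("selfpool")
  l$d_in <- d_in
  l$par <- list(q = rnorm(d_in, 0, sqrt(1 / d_in)))
  l$fwd <- function(x, training = FALSE) {
    L <- attr(x, "L"); B <- ncol(x) / L
    s <- crossprod(x, l$par$q)[, 1] / sqrt(l$d_in)
    a <- softmax_cols(matrix(s, L, B))
    av <- as.vector(a)
    xw <- x * rep(av, each = l$d_in)
    out <- t(rowsum(t(xw), rep(seq_len(B), each = L), reorder = FALSE))
    l$cache <- list(x = x, a = a, L = L, B = B)
    seq_attr(out, 1L)
  }
  l$bwd <- function(dy) {
    cc <- l$cache
    L <- cc$L; B <- cc$B; d <- l$d_in
    gb <- rep(seq_len(B), each = L)
    av <- as.vector(cc$a)
    dx <- dy[, gb, drop = FALSE] * rep(av, each = d)
    dalpha <- matrix(colSums(cc$x * dy[, gb, drop = FALSE]), L, B)
    ds <- cc$a * (dalpha - rep(colSums(cc$a * dalpha), each = L))
    dsv <- as.vector(ds) / sqrt(d)
    l$grad$q <- l$grad$q + as.vector(cc$x %*% dsv)
    dx <- dx + tcrossprod(l$par$q, dsv)
    seq_attr(dx, L)
  }
  l
}

# ---- containers -----------------------------------------------------------

nn_seq <- function(...) {
  l <- new_nn_layer("seq")
  l$layers <- list(...)
  if (length(l$layers) == 1 && is.list(l$layers[[1]]) && !inherits(l$layers[[1]], "nn_layer")) {
    l$layers <- l$layers[[1]]
  }
  l$fwd <- function(x, training = FALSE) {
    for (sub in l$layers) x <- sub$fwd(x, training)
    x
  }
  l$bwd <- function(dy) {
    for (sub in rev(l$layers)) dy <- sub$bwd(dy)
    dy
  }
  l
}

# parallel branches on the same input, outputs concatenated channel-wise
nn_parallel_concat <- function(branches) {
  l <- new_nn_layer("parallel_concat")
  l$branches <- branches
  l$fwd <- function(x, training = FALSE) {
    ys <- lapply(l$branches, function(br) br$fwd(x, training))
    l$cache <- vapply(ys, nrow, integer(1))
    seq_attr(do.call(rbind, ys), attr(ys[[1]], "L"))
  }
  l$bwd <- function(dy) {
    sizes <- l$cache
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1
    dx <- NULL
    for (i in seq_along(l$branches)) {
      d <- l$branches[[i]]$bwd(seq_attr(dy[starts[i]:ends[i], , drop = FALSE], attr(dy, "L")))
      dx <- if (is.null(dx)) d else seq_attr(dx + d, attr(d, "L"))
    }
    dx
  }
  l
}

# sum of branch outputs (residual connections), optional trailing ReLU
nn_add <- function(branches, post_relu = TRUE) {
  l <- new_nn_layer("add")
  l$branches <- branches
  l$post_relu <- post_relu
  l$fwd <- function(x, training = FALSE) {
    ys <- lapply(l$branches, function(br) br$fwd(x, training))
    y <- Reduce(`+`, ys)
    if (l$post_relu) {
      l$cache <- y > 0
      y <- y * l$cache
    }
    seq_attr(y, attr(ys[[1]], "L"))
  }
  l$bwd <- function(dy) {
    if (l$post_relu) dy <- seq_attr(dy * l$cache, attr(dy, "L"))
    dx <- NULL
    for (br in l$branches) {
      d <- br$bwd(dy)
      dx <- if (is.null(dx)) d else seq_attr(dx + d, attr(d, "L"))
    }
    dx
  }
  l
}

nn_identity <- function() {
  l <- new_nn_layer("identity")
  l$fwd <- function(x, training = FALSE) x
  l$bwd <- function(dy) dy
  l
}

# ---- loss -----------------------------------------------------------------

# class-weighted softmax cross-entropy; logits: 2 x B, y in {0, 1}
softmax_xent <- function(logits, y, class_w = c(1, 1)) {
  B <- ncol(logits)
  p <- softmax_cols(logits)
  wy <- class_w[y + 1]
  picked <- p[cbind(y + 1, seq_len(B))]
  loss <- sum(-log(pmax(picked, 1e-12)) * wy) / sum(wy)
  dlogits <- p
  dlogits[cbind(y + 1, seq_len(B))] <- dlogits[cbind(y + 1, seq_len(B))] - 1
  dlogits <- dlogits * rep(wy / sum(wy), each = 2)
  list(loss = loss, dlogits = seq_attr(dlogits, 1L), probs = p)
}
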