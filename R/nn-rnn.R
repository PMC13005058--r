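# Recurrent layers (GRU / LSTM) with full backpropagation through time.
# Input projections for all timesteps are computed as one GEMM; only the
# recurrent part loops over time.

nn_gru <- function(in_ch, hidden = 64L, return_seq = FALSE) {
  l <- new_nn_layer("gru")
  l$in_ch <- in_ch; l$H <- as.integer(hidden); l$return_seq <- return_seq
  s <- 1 / sqrt(hidden)
  H <- l$H
  l$par <- list(
    W = matrix(runif(3 * H * in_ch, -s, s), 3 * H, in_ch), # input weights [z; r; n]
    U = matrix(runif(3 * H * H, -s, s), 3 * H, H),         # recurrent weights
    b = runif(3 * H, -s, s)
  )
  iz <- 1:H; ir <- (H + 1):(2 * H); inn <- (2 * H + 1):(3 * H)

  l$fwd <- function(x, training = FALSE) {
    L <- attr(x, "L"); B <- ncol(x) / L
    H <- l$H
    wx <- l$par$W %*% x + l$par$b
    h <- matrix(0, H, B)
    hs <- matrix(0, H, B * L)
    zs <- matrix(0, H, B * L); rs <- matrix(0, H, B * L)
    ns <- matrix(0, H, B * L); unh <- matrix(0, H, B * L)
    cols_t <- function(t) (seq_len(B) - 1) * L + t
    for (t in seq_len(L)) {
      ct <- cols_t(t)
      uh <- l$par$U %*% h
      z <- 1 / (1 + exp(-(wx[iz, ct, drop = FALSE] + uh[iz, , drop = FALSE])))
      r <- 1 / (1 + exp(-(wx[ir, ct, drop = FALSE] + uh[ir, , drop = FALSE])))
      un <- uh[inn, , drop = FALSE]
      nn <- tanh(wx[inn, ct, drop = FALSE] + r * un)
      h <- (1 - z) * nn + z * h
      hs[, ct] <- h; zs[, ct] <- z; rs[, ct] <- r; ns[, ct] <- nn; unh[, ct] <- un
    }
    l$cache <- list(x = x, hs = hs, zs = zs, rs = rs, ns = ns, unh = unh, L = L, B = B)
    if (l$return_seq) seq_attr(hs, L) else seq_attr(hs[, cols_t(L), drop = FALSE], 1L)
  }

  l$bwd <- function(dy) {
    cc <- l$cache
    L <- cc$L; B <- cc$B; H <- l$H
    cols_t <- function(t) (seq_len(B) - 1) * L + t
    dwx <- matrix(0, 3 * H, B * L)
    dU <- matrix(0, 3 * H, H)
    dh <- matrix(0, H, B)
    dy_seq <- if (l$return_seq) dy else NULL
    if (!l$return_seq) dh <- dh + dy
    for (t in rev(seq_len(L))) {
      ct <- cols_t(t)
      if (!is.null(dy_seq)) dh <- dh + dy_seq[, ct, drop = FALSE]
      z <- cc$zs[, ct, drop = FALSE]; r <- cc$rs[, ct, drop = FALSE]
      nn <- cc$ns[, ct, drop = FALSE]; un <- cc$unh[, ct, drop = FALSE]
      h_prev <- if (t > 1) cc$hs[, cols_t(t - 1), drop = FALSE] else matrix(0, H, B)
      dn <- dh * (1 - z)
      dz <- dh * (h_prev - nn)
      dh_new <- dh * z
      da_n <- dn * (1 - nn^2)
      dr <- da_n * un
      da_z <- dz * z * (1 - z)
      da_r <- dr * r * (1 - r)
      dwx[iz, ct] <- da_z; dwx[ir, ct] <- da_r; dwx[inn, ct] <- da_n
      dU[iz, ] <- dU[iz, ] + da_z %*% t(h_prev)
      dU[ir, ] <- dU[ir, ] + da_r %*% t(h_prev)
      dU[inn, ] <- dU[inn, ] + (da_n * r) %*% t(h_prev)
      dh <- dh_new +
        crossprod(l$par$U[iz, , drop = FALSE], da_z) +
        crossprod(l$par$U[ir, , drop = FALSE], da_r) +
        crossprod(l$par$U[inn, , drop = FALSE], da_n * r)
    }
    l$grad$W <- l$grad$W + tcrossprod(dwx, cc$x)
    l$grad$U <- l$grad$U + dU
    l$grad$b <- l$grad$b + rowSums(dwx)
    seq_attr(crossprod(l$par$W, dwx), L)
  }
  l
}

nn_lstm <- function(in_ch, hidden = 64L, return_seq = FALSE) {
  l <- new_nn_layer("lstm")
  l$in_ch <- in_ch; l$H <- as.integer(hidden); l$return_seq <- return_seq
  s <- 1 / sqrt(hidden)
  H <- l$H
  l$par <- list(
    W = matrix(runif(4 * H * in_ch, -s, s), 4 * H, in_ch), # [i; f; g; o]
    U = matrix(runif(4 * H * H, -s, s), 4 * H, H),
    b = c(runif(H, -s, s), runif(H, -s, s) + 1, runif(2 * H, -s, s)) # forget bias +1
  )
  ii <- 1:H; iff <- (H + 1):(2 * H); ig <- (2 * H + 1):(3 * H); io <- (3 * H + 1):(4 * H)

  l$fwd <- function(x, training = FALSE) {
    L <- attr(x, "L"); B <- ncol(x) / L
    H <- l$H
    wx <- l$par$W %*% x + l$par$b
    h <- matrix(0, H, B); cs <- matrix(0, H, B)
    hs <- matrix(0, H, B * L)
    gates <- matrix(0, 4 * H, B * L)
    cells <- matrix(0, H, B * L)
    cols_t <- function(t) (seq_len(B) - 1) * L + t
    for (t in seq_len(L)) {
      ct <- cols_t(t)
      a <- wx[, ct, drop = FALSE] + l$par$U %*% h
      i <- 1 / (1 + exp(-a[ii, , drop = FALSE]))
      f <- 1 / (1 + exp(-a[iff, , drop = FALSE]))
      g <- tanh(a[ig, , drop = FALSE])
      o <- 1 / (1 + exp(-a[io, , drop = FALSE]))
      cs <- f * cs + i * g
      h <- o * tanh(cs)
      hs[, ct] <- h
      gates[ii, ct] <- i; gates[iff, ct] <- f; gates[ig, ct] <- g; gates[io, ct] <- o
      cells[, ct] <- cs
    }
    l$cache <- list(x = x, hs = hs, gates = gates, cells = cells, L = L, B = B)
    if (l$return_seq) seq_attr(hs, L) else seq_attr(hs[, cols_t(L), drop = FALSE], 1L)
  }

  l$bwd <- function(dy) {
    cc <- l$cache
    L <- cc$L; B <- cc$B; H <- l$H
    cols_t <- function(t) (seq_len(B) - 1) * L + t
    da_all <- matrix(0, 4 * H, B * L)
    dU <- matrix(0, 4 * H, H)
    dh <- matrix(0, H, B); dc <- matrix(0, H, B)
    dy_seq <- if (l$return_seq) dy else NULL
    if (!l$return_seq) dh <- dh + dy
    for (t in rev(seq_len(L))) {
      ct <- cols_t(t)
      if (!is.null(dy_seq)) dh <- dh + dy_seq[, ct, drop = FALSE]
      i <- cc$gates[ii, ct, drop = FALSE]; f <- cc$gates[iff, ct, drop = FALSE]
      g <- cc$gates[ig, ct, drop = FALSE]; o <- cc$gates[io, ct, drop = FALSE]
      cs <- cc$cells[, ct, drop = FALSE]
      c_prev <- if (t > 1) cc$cells[, cols_t(t - 1), drop = FALSE] else matrix(0, H, B)
      h_prev <- if (t > 1) cc$hs[, cols_t(t - 1), drop = FALSE] else matrix(0, H, B)
      tc <- tanh(cs)
      do_ <- dh * tc
      dc <- dc + dh * o * (1 - tc^2)
      di <- dc * g; df <- dc * c_prev; dg <- dc * i
      da <- rbind(
        di * i * (1 - i),
        df * f * (1 - f),
        dg * (1 - g^2),
        do_ * o * (1 - o)
      )
      da_all[, ct] <- da
      dU <- dU + da %*% t(h_prev)
      dh <- crossprod(l$par$U, da)
      dc <- dc * f
    }
    l$grad$W <- l$grad$W + tcrossprod(da_all, cc$x)
    l$grad$U <- l$grad$U + dU
    l$grad$b <- l$grad$b + rowSums(da_all)
    seq_attr(crossprod(l$par$W, da_all), L)
  }
  l
}
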