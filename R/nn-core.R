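# Minimal recurrent-network engine: batched LSTM forward/backward passes and
# an Adam optimizer, written against base-R matrix algebra. Sequences are
# lists of B x D matrices (one per time step); gate blocks are ordered
# input, forget, cell, output within the 4M weight columns.

.sigm <- function(z) 1 / (1 + exp(-z))
.relu <- function(z) z * (z > 0)

.softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

.init_mat <- function(nr, nc, r) matrix(stats::runif(nr * nc, -r, r), nr, nc)

# One LSTM direction: Wx (D x 4M), Wh (M x 4M), b (1 x 4M); forget bias +1.
lstm_init <- function(input_dim, hidden) {
  r <- 1 / sqrt(hidden)
  b <- matrix(0, 1, 4L * hidden)
  b[1, hidden + seq_len(hidden)] <- 1
  list(Wx = .init_mat(input_dim, 4L * hidden, r),
       Wh = .init_mat(hidden, 4L * hidden, r),
       b = b)
}

# Xs: list of s matrices (B x D). reverse = TRUE processes t = s..1; outputs
# stay aligned to the original positions (H[[t]] is the state after the cell
# has consumed step t in its own direction).
lstm_seq_forward <- function(Xs, p, reverse = FALSE) {
  s <- length(Xs)
  B <- nrow(Xs[[1L]])
  M <- nrow(p$Wh)
  ord <- if (reverse) s:1 else 1:s
  bmat <- matrix(p$b, B, 4L * M, byrow = TRUE)
  h <- matrix(0, B, M); cc <- matrix(0, B, M)
  H <- vector("list", s); cache <- vector("list", s)
  ii <- seq_len(M); ff <- M + ii; gg <- 2L * M + ii; oo <- 3L * M + ii
  for (t in ord) {
    Z <- Xs[[t]] %*% p$Wx + h %*% p$Wh + bmat
    i <- .sigm(Z[, ii, drop = FALSE])
    f <- .sigm(Z[, ff, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE])
    o <- .sigm(Z[, oo, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(x = Xs[[t]], h_prev = h, c_prev = cc,
                       i = i, f = f, g = g, o = o, tc = tc)
    cc <- c_new
    h <- o * tc
    H[[t]] <- h
  }
  list(H = H, h_last = h, cache = cache, reverse = reverse, M = M)
}

# dH: list of B x M gradients w.r.t. each output state (NULL = zero).
lstm_seq_backward <- function(dH, fwd, p) {
  s <- length(fwd$cache)
  B <- nrow(fwd$cache[[1L]]$h_prev)
  M <- fwd$M
  ord <- if (fwd$reverse) 1:s else s:1
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh_next <- matrix(0, B, M); dc_next <- matrix(0, B, M)
  dX <- vector("list", s)
  tWx <- t(p$Wx); tWh <- t(p$Wh)
  for (t in ord) {
    ca <- fwd$cache[[t]]
    dh <- dh_next
    if (!is.null(dH[[t]])) dh <- dh + dH[[t]]
    do_ <- dh * ca$tc
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$c_prev
    dc_next <- dc * ca$f
    dZ <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(ca$x, dZ)
    dWh <- dWh + crossprod(ca$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[[t]] <- dZ %*% tWx
    dh_next <- dZ %*% tWh
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

## ---- Adam ----------------------------------------------------------------

# params/grads are nested named lists of numeric matrices/vectors.
adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
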